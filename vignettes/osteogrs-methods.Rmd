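---
title: "Methods: LASSO-weighted genetic risk scores for fracture and BMD prediction"
author: "osteogrs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LASSO-weighted genetic risk scores for fracture and BMD prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteogrs)
options(osteogrs.verbose = 0)
```

## The scientific question

Osteoporotic fracture risk is routinely assessed from clinical risk
factors (CRFs) — gender, age, height, weight — and genome-wide
association studies, performed predominantly in populations of European
descent, have nominated many genes for fracture and for bone mineral
density (BMD). Whether a genetic risk score (GRS) built from those genes
improves risk prediction in a *different* ancestry group (here, Chinese
Han cohorts) is an empirical question: allele frequencies, linkage
disequilibrium (LD) structure and effect sizes may not transfer across
populations. osteogrs implements the full evaluation pipeline for this
question — gene-based SNP-set selection, risk-allele orientation,
L1-penalised weight learning under cross-validation, and the
discrimination/reclassification statistics used to judge whether the GRS
adds anything over CRFs alone — together with a synthetic-cohort
generator whose *transferability* parameter makes the cross-ancestry
hypothesis directly testable end to end.

## Genetic risk score construction

Within each training set:

1. **Risk-allele orientation.** Each SNP's dosage counts one coded
   allele (0/1/2). The dosage is recoded to `2 - g` whenever its
   marginal association (the sign of `cov(g, y)`, a score-statistic
   sign) points away from risk — i.e. toward protection for fracture,
   or toward *higher* BMD for the quantitative trait — so every counted
   allele points toward higher fracture risk / lower BMD. A zero
   association leaves the coding unchanged. Flags are stored and
   re-applied verbatim to held-out subjects.
2. **Penalty choice.** The LASSO penalty is selected by an inner
   5-fold cross-validation over a logarithmic grid from
   `lambda_max` (the smallest penalty that zeroes every coefficient)
   down to `lambda_max / 1000`, taking the *largest* penalty within one
   standard error of the minimum CV deviance. The 1-SE rule is a
   deliberate parsimony tie-break: sparse scores transfer better and
   make the downstream single-degree-of-freedom GRS term interpretable.
3. **Weight estimation.** Coefficients minimise the L1-penalised
   squared-error loss (BMD) or logistic deviance (fracture; a linear
   fit on a 0/1 outcome would not match the downstream logistic model
   family), with an unpenalised intercept and internally standardised
   columns, solved by cyclic coordinate descent (glmnet). Coefficients
   are reported on the original dosage scale.
4. **Scoring.** `GRS_i = sum_j w_j g_ij` over the risk-oriented
   dosages. Zero-weight SNPs drop out; if *every* weight is zero the
   score is uninformative and downstream models fall back to the same
   specification without the GRS term (its coefficient is recorded as
   zero) rather than failing on a constant covariate.

## Gene-based SNP-set selection (extended Simes / GATES)

When the SNP panel is not fixed a priori, genes are screened by the
extended Simes procedure: with a gene's per-SNP p-values sorted
ascending,

`p_gene = min_j ( m_e * p_(j) / m_e(j) )`

where `m_e` is the effective number of independent tests among all `m`
SNPs and `m_e(j)` the same quantity over the `j` most significant ones.
Effective counts come from the eigenvalues of the p-value correlation
matrix, `m_e = m - sum_{lambda_i > 1} (lambda_i - 1)`, and the p-value
correlation is approximated from the dosage correlation `r` by the
sixth-degree polynomial
`0.2982|r|^6 - 0.0127|r|^5 + 0.0588|r|^4 + 0.0099|r|^3 + 0.6281|r|^2 -
0.0009|r|`. Two numerical choices are ours: the polynomial is applied to
`|r|` (two-sided tests are direction-blind), and entries with `|r| = 1`
are snapped to exactly 1 — duplicated SNPs carry identical p-values, and
the raw polynomial value of 0.9814 at `|r| = 1` would leave a perfectly
redundant gene with `m_e > 1`. With independent SNPs the statistic
reduces to the Simes combination; with perfectly correlated SNPs it
returns the minimum p unpenalised. Genes pass at `p_gene` strictly below
the threshold (default `2e-6`, a conventional gene-based genome-wide
level); the LD panel is the analysis cohort's own genotypes, the only
in-scope source. Ties in SNP p-values are broken by SNP id so the
reported SNP ordering is deterministic.

## Risk models and cross-validation

Six regression models are predefined. In the case-control sample:
logistic `fracture ~ CRFs` (I-I), `~ CRFs + GRS_F` (I-II), `~ CRFs +
GRS_B` (I-III); in the population sample: linear `BMD ~ CRFs` (II-I),
`~ GRS_B` (II-II), `~ CRFs + GRS_B` (II-III). GRS_F and GRS_B differ by
their SNP panel (fracture-associated versus BMD-associated genes);
inside the case-control sample both are necessarily trained against the
fracture outcome, since no BMD phenotype exists there — the panel, not
the training outcome, distinguishes them.

Evaluation uses 10-fold cross-validation. Folds are stratified by case
status for binary outcomes (simple random folds otherwise — the
published design is silent on stratification, and stratification is the
only choice that guarantees two-class folds at these sample sizes);
subjects are canonicalised by id before partitioning so fold membership
is invariant to row order; and one fold assignment is shared by all
models in a run so comparisons are paired. *Everything* — orientation
flags, the inner-CV penalty, LASSO weights, regression coefficients — is
computed on the nine training folds only; the tests mutate held-out rows
and assert bit-identical fold models to enforce this.

## Evaluation statistics

**AUC** is computed in Mann-Whitney form from midranks: the probability
that a random event outranks a random non-event, ties counted one half.

**Reclassification and NRI.** Predicted fracture probabilities are
binned into lower (`p < 0.10`), middle (`0.10 <= p < 0.15`) and higher
(`p >= 0.15`) risk groups. The bands are half-open with the upper
boundary owned by the higher group — the only reading consistent with
"below 10%" and "15% and above". Cross-tabulating baseline versus
augmented categories separately for events and non-events gives the two
3x3 tables, and

`NRI = Pr(up|event) - Pr(down|event) + Pr(down|non-event) - Pr(up|non-event)`

with `up`/`down` strict category movements. Significance uses the
standard asymptotic test,
`z = NRI / sqrt((p_up^e + p_down^e)/n_e + (p_up^ne + p_down^ne)/n_ne)`,
two-sided normal. Zero movement yields `z = 0, p = 1` by convention.
Report percentages are printed at two decimals, rounding half away from
zero; exact fractions are always carried alongside, because combining
independently rounded two-decimal components can differ from the rounded
exact NRI in the last digit (published tables show exactly this
behaviour, e.g. 1/350 appearing as 0.30%), and
`combine_printed_components()` exists to reproduce such printed sums.

**MSE comparison.** For the linear models, per-fold test-set mean
squared errors are compared by a two-sided paired t-test on the ten
fold-level differences (pairing per fold, not per subject: fold MSEs are
the natural exchangeable unit under a shared fold assignment). All-zero
differences give `t = 0, p = 1` rather than an error.

**Relative importance.** The share of explained variation attributed to
each predictor is the Shapley/LMG decomposition: the average, over all
predictor orderings, of the predictor's sequential increment to R²
(linear) or McFadden pseudo-R² (logistic). No published name pins down
"relative importance" in this setting; the ordering average is the
defensible canonical choice, is labelled as such in output, and has two
exact properties the tests verify — shares are non-negative (sequential
increments of explained variation never decrease) and sum to the full
model's explained variation.

## The synthetic-cohort generator

Since the original cohorts are not deposited, the pipeline is exercised
on synthetic cohorts built to the same design.

**Genotypes.** SNPs come in gene blocks. Per gene and per haplotype
layer, a Gaussian copula with exchangeable latent correlation `ld_rho`
is thresholded at the Hardy-Weinberg quantile of a MAF drawn uniformly
from `maf_range` (default 0.05-0.5); the dosage is the sum of two
independent layers. This keeps every SNP marginally Hardy-Weinberg at
its MAF while a single parameter controls LD; genes are mutually
independent.

**Phenotypes.** CRFs are drawn independently per subject: gender
Bernoulli(0.5); age, height, weight normal with means/SDs set to the
emulated sample — 70.56 ± 7.74 y, 160.70 ± 8.97 cm, 59.34 ± 10.68 kg
for the elderly case-control design (n = 700, 350 cases), and
34.46 ± 13.24 y, 164.26 ± 8.17 cm, 60.10 ± 10.48 kg with FN-BMD
0.920 ± 0.133 g/cm² for the population design (n = 1,620). Height and
weight get a fixed male-female mean offset (11 cm / 8 kg split evenly
around the overall mean); beyond that CRFs are independent, a stated
simplification. Draws are truncated below at zero by redraw (< 0.5%
of mass), keeping CRFs physically valid without visibly distorting the
moments.

**Effects and transferability.** A fraction `frac_causal` (default 0.2)
of SNPs receive effects drawn `Normal(0, snp_effect_sd)`; all SNP
effects are then multiplied by the transferability factor `tau` in
`[0, 1]`. `tau = 1` means discovery-population effects carry over
fully; `tau = 0` means none transfer — the generative analogue of
European-derived weights being uninformative in the target population.
CRF and genetic contributions enter the linear predictor centred at
their population means, so `intercept` (0.920 g/cm²) and `base_logodds`
(logit 0.10) are the trait mean and baseline fracture log-odds at mean
covariates. Quantitative defaults (`snp_effect_sd = 0.01 g/cm²` per
allele, `noise_sd = 0.12`) were chosen once so that CRF, genetic and
residual variance components add up to approximately the observed
FN-BMD dispersion of 0.133 g/cm²; fracture defaults use CRF log-odds
matching the published odds ratios (1.808 female gender, 1.036/y,
1.017/cm, 0.990/kg). A companion lumbar-spine BMD (mean 0.948) is
emitted with correlation about 0.7 to FN-BMD. Case-control cohorts are
drawn by rejection from the population model until exactly
`round(n * case_fraction)` cases and the complementary controls are
collected (capped at 1000 draws per case-quota unit, then an error) —
matching a designed case-control study rather than a cohort sample.

What the generator does *not* emulate: imputation uncertainty,
genotyping error, population stratification, relatedness, CRF
correlations (e.g. height-weight), or realistic genome-scale LD. Passing
tests therefore demonstrate that the *pipeline machinery* behaves as
specified under a faithful statistical idealisation of the study design,
not that any particular real-data result would replicate.

## Reproducibility and numerics

One top-level integer seed fans out to named sub-seeds (simulation, fold
assignment, each fold's inner CV) through a deterministic hash, so a
single number reproduces an entire experiment; `run_experiment()` writes
its resolved configuration with an MD5 hash and re-running an identical
configuration yields byte-identical reports. Coordinate descent runs to
a coefficient tolerance of 1e-12 (tests hold the unpenalised limit and
the orthonormal soft-threshold closed form to 1e-6). Degenerate inputs
have defined behaviour throughout: constant outcomes, monomorphic SNPs,
empty genes, single-class folds, perfect separation and singular designs
raise informative errors; all-zero LASSO weights trigger the documented
GRS-drop fallback.

## Problem sizes used in the packaged experiments

The packaged acceptance analysis runs the transferability experiment at
the study design size (700 subjects, 100 SNPs in 20 genes, 10-fold CV,
20 replicate seeds per `tau`) and the BMD comparison at n = 1,620; unit
tests use smaller cohorts (60-700 subjects) chosen to keep the full
suite fast while leaving every code path exercised at the design sample
sizes somewhere in the suite.

## Known limitations

* The GATES p-value correlation polynomial is an approximation fitted
  for common-variant LD; rare variants or non-Pearson LD measures are
  out of scope.
* Only biallelic, fully observed genotypes are accepted; imputation is
  deliberately upstream of this package.
* The relative-importance decomposition enumerates predictor subsets
  (2^p fits) and is intended for the handful of predictors used here,
  not for wide models.
* `NRI` is the categorical (three-band) version; continuous NRI and IDI
  are not implemented.
* In a balanced case-control sample the pooled out-of-fold
  probabilities centre near 0.5, so the clinical 10%/15% bands can
  classify nearly everyone as higher risk and leave the categorical NRI
  at zero. Reclassification there is most informative with cutoffs
  adapted to the sample's predicted-risk distribution
  (`risk_cutoffs` in the experiment config).
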