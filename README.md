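# osteogrs

Builds and evaluates **LASSO-weighted genetic risk scores (GRS)** for
osteoporotic fracture and bone mineral density (BMD) prediction, and
asks the question such scores exist to answer: *does adding the GRS to
clinical risk factors (CRFs: gender, age, height, weight) actually
improve prediction?* The package targets the cross-ancestry setting —
gene panels discovered in one population, evaluated in another — and
ships a synthetic-cohort generator whose transferability parameter
`tau` lets that scenario be simulated end to end.

## What it computes

* **Gene-based SNP-set selection** by the extended Simes procedure
  (GATES): gene p-value `min_j m_e p_(j) / m_e(j)` with eigenvalue-based
  effective test counts `m_e = m − Σ_{λ_i>1}(λ_i − 1)` from LD-derived
  p-value correlations; threshold selection (default `p < 2e-6`).
* **GRS construction**: risk-allele orientation (each dosage recoded so
  the counted allele tracks higher fracture risk / lower BMD), LASSO
  weights with the penalty chosen by inner 5-fold CV under the
  one-standard-error rule, and the scalar score
  `GRS_i = Σ_j w_j g_ij`.
* **Risk models**: logistic `fracture ~ CRFs (+ GRS)` and linear
  `BMD ~ CRFs/GRS`, evaluated by 10-fold cross-validation with
  stratified, paired fold assignments and strictly leakage-free
  per-fold training.
* **Evaluation**: Mann-Whitney AUC; 3×3 risk-group reclassification
  tables (bands `<10%`, `10–15%`, `≥15%`); the net reclassification
  improvement `NRI = Pr(up|event) − Pr(down|event) + Pr(down|non-event)
  − Pr(up|non-event)` with its asymptotic Z-test; paired fold-level MSE
  t-tests for the linear models; and a Shapley/LMG relative-importance
  decomposition of explained variation.

## Worked example

Simulate a 350-case/350-control cohort in which *no* SNP effects
transfer (`transfer_tau = 0`), then ask whether a cross-validated GRS
adds discrimination over CRFs alone:

```r
library(osteogrs)

co <- simulate_casecontrol_cohort(
  simulation_config("fracture", transfer_tau = 0, seed = 42))
cv <- cross_validate(co, c("I-I", "I-II"), seed = 42)
y  <- co$phenotypes$fracture
auc(cv[["I-I"]]$oof_prediction, y)   # CRFs only
auc(cv[["I-II"]]$oof_prediction, y)  # CRFs + GRS
```

```
AUC  I-I (CRFs only):  0.570
AUC  I-II (CRFs+GRS):  0.573
```

With `tau = 0` the learned weights carry noise, so the GRS adds nothing
beyond chance fluctuation (averaged over seeds the gain is ~0); with
`tau = 1` and strong effects the same pipeline shows a clearly positive
gain. Published reclassification tables can be checked directly from
their printed counts:

```r
t5_event    <- matrix(c(88,0,0, 0,110,0, 0,4,148), 3, 3, byrow = TRUE)
t5_nonevent <- matrix(c(76,0,0, 0,102,1, 1,6,164), 3, 3, byrow = TRUE)
str(verify_tables(t5_event, t5_nonevent)$computed)
```

```
List of 10
 $ up_event_pct     : num 0
 $ down_event_pct   : num 1.14
 $ up_nonevent_pct  : num 0.29
 $ down_nonevent_pct: num 2
 $ event_net_pct    : num -1.14
 $ nonevent_net_pct : num 1.71
 $ nri_exact        : num 0.00571
 $ nri_exact_pct    : num 0.571
 $ z                : num 0.577
 $ p_value          : num 0.564
```

Among 350 fractures, 4 subjects (1.14%) were reclassified downward and
none upward; among 350 non-fractures, 7 (2.00%) moved down and 1 up.
The exact-fraction NRI is 2/350 ≈ 0.57% with Z = 0.577 (p = 0.56):
no significant reclassification benefit.

Whole experiments run from a YAML config (`run_experiment()`), and a
thin CLI sits in `inst/cli/osteogrs` with subcommands `simulate`,
`select-genes`, `run` and `verify-tables`. Reports are deterministic:
the same config and seed reproduce the bundle byte for byte.

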