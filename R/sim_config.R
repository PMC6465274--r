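#' Simulation configuration for synthetic cohorts
#'
#' Defines the generating model for synthetic genotype/phenotype cohorts:
#' LD-blocked genotypes in Hardy-Weinberg equilibrium, clinical risk
#' factors (CRFs: gender, age, height, weight), per-SNP additive effects,
#' and a cross-population transferability multiplier `transfer_tau` that
#' attenuates SNP effects in the target population (`transfer_tau = 0`
#' models complete non-transfer of discovery-population effects).
#'
#' Defaults emulate one of two study designs:
#' * `sample = "fracture"`: an elderly case-control sample of 700 subjects
#'   (350 hip-fracture cases, 350 controls; age 70.56 +/- 7.74 y,
#'   height 160.70 +/- 8.97 cm, weight 59.34 +/- 10.68 kg). Default CRF
#'   log-odds effects correspond to odds ratios 1.808 (female gender),
#'   1.036 per year of age, 1.017 per cm, 0.990 per kg.
#' * `sample = "bmd"`: a population sample of 1,620 adults with measured
#'   femoral-neck BMD (age 34.46 +/- 13.24 y, height 164.26 +/- 8.17 cm,
#'   weight 60.10 +/- 10.48 kg; FN-BMD 0.920 +/- 0.133 g/cm^2).
#'
#' @param sample Which study design the defaults emulate: `"bmd"` or
#'   `"fracture"`.
#' @param n_subjects Number of subjects.
#' @param n_genes,snps_per_gene Genotype layout: `n_genes` LD blocks of
#'   `snps_per_gene` SNPs each.
#' @param maf_range Length-2 numeric, minor-allele-frequency range in
#'   `(0, 0.5]`; each SNP's MAF is drawn uniformly from it.
#' @param ld_rho Within-gene latent (haplotype-level) correlation in
#'   `[0, 1)` of the Gaussian copula generating LD.
#' @param snp_effect_sd Scale (SD) of nonzero per-SNP effects: trait units
#'   per coded allele (g/cm^2 for BMD, log-odds for fracture).
#' @param frac_causal Fraction of SNPs with a nonzero effect, in `[0, 1]`.
#' @param crf_effects Named numeric of length 4, coefficients for
#'   `gender` (1 = female), `age` (per year), `height` (per cm), `weight`
#'   (per kg), on the trait/log-odds scale.
#' @param noise_sd Residual SD of the quantitative trait (g/cm^2).
#' @param transfer_tau Effect-transferability multiplier in `[0, 1]`
#'   applied to all SNP effects in the generated (target) population.
#' @param case_fraction Target case share for case-control sampling.
#' @param seed Integer seed; identical configs generate bit-identical
#'   cohorts.
#' @param intercept Quantitative-trait intercept (mean FN-BMD, g/cm^2).
#' @param base_logodds Population baseline log-odds of fracture before
#'   CRF/SNP contributions (defaults to `qlogis(0.10)`).
#' @param crf_means,crf_sds Named numerics (`age`, `height`, `weight`)
#'   giving CRF population means/SDs.
#' @param gender_shift Named numeric (`height`, `weight`): total
#'   male-minus-female difference in CRF means; each gender's mean is the
#'   overall mean +/- half the shift.
#' @param ls_bmd_cor Correlation between the generated femoral-neck and
#'   lumbar-spine BMD values (LS-BMD is emitted as a companion trait).
#' @return A validated list of class `SimulationConfig`.
#' @export
#' @examples
#' cfg <- simulation_config("bmd", n_subjects = 200, seed = 7)
#' cfg$n_subjects
simulation_config <- function(sample = c("bmd", "fracture"),
                              n_subjects = NULL,
                              n_genes = 20L,
                              snps_per_gene = 5L,
                              maf_range = c(0.05, 0.5),
                              ld_rho = 0.5,
                              snp_effect_sd = NULL,
                              frac_causal = 0.2,
                              crf_effects = NULL,
                              noise_sd = NULL,
                              transfer_tau = 1,
                              case_fraction = 0.5,
                              seed = 1L,
                              intercept = 0.920,
                              base_logodds = qlogis(0.10),
                              crf_means = NULL,
                              crf_sds = NULL,
                              gender_shift = c(height = 11, weight = 8),
                              ls_bmd_cor = 0.7) {
  sample <- match.arg(sample)
  if (sample == "bmd") {
    n_subjects <- n_subjects %||% 1620L
    crf_means <- crf_means %||% c(age = 34.46, height = 164.26, weight = 60.10)
    crf_sds <- crf_sds %||% c(age = 13.24, height = 8.17, weight = 10.48)
    crf_effects <- crf_effects %||%
      c(gender = -0.050, age = -0.002, height = 0.0005, weight = 0.003)
    snp_effect_sd <- snp_effect_sd %||% 0.010
    noise_sd <- noise_sd %||% 0.12
  } else {
    n_subjects <- n_subjects %||% 700L
    crf_means <- crf_means %||% c(age = 70.56, height = 160.70, weight = 59.34)
    crf_sds <- crf_sds %||% c(age = 7.74, height = 8.97, weight = 10.68)
    crf_effects <- crf_effects %||%
      c(gender = log(1.808), age = log(1.036),
        height = log(1.017), weight = log(0.990))
    snp_effect_sd <- snp_effect_sd %||% 0.08
    noise_sd <- noise_sd %||% 0  # latent logistic noise is implicit
  }
  cfg <- list(
    sample = sample, n_subjects = n_subjects, n_genes = n_genes,
    snps_per_gene = snps_per_gene, maf_range = maf_range, ld_rho = ld_rho,
    snp_effect_sd = snp_effect_sd, frac_causal = frac_causal,
    crf_effects = crf_effects, noise_sd = noise_sd,
    transfer_tau = transfer_tau, case_fraction = case_fraction,
    seed = as.integer(seed), intercept = intercept,
    base_logodds = base_logodds, crf_means = crf_means, crf_sds = crf_sds,
    gender_shift = gender_shift, ls_bmd_cor = ls_bmd_cor
  )
  validate_sim_config(cfg)
  structure(cfg, class = "SimulationConfig")
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_subjects)) stop_("n_subjects must be a positive integer")
  if (!is_count(cfg$n_genes)) stop_("n_genes must be a positive integer")
  if (!is_count(cfg$snps_per_gene)) {
    stop_("snps_per_gene must be a positive integer")
  }
  mr <- cfg$maf_range
  if (!is.numeric(mr) || length(mr) != 2L || mr[1] > mr[2] ||
      mr[1] <= 0 || mr[2] > 0.5) {
    stop_("maf_range must lie within (0, 0.5] with maf_range[1] <= maf_range[2]")
  }
  if (!is.numeric(cfg$ld_rho) || cfg$ld_rho < 0 || cfg$ld_rho >= 1) {
    stop_("ld_rho must be in [0, 1)")
  }
  if (!is_prob(cfg$frac_causal)) stop_("frac_causal must be in [0, 1]")
  if (!is_prob(cfg$transfer_tau)) stop_("transfer_tau must be in [0, 1]")
  if (!is.numeric(cfg$case_fraction) || cfg$case_fraction <= 0 ||
      cfg$case_fraction >= 1) {
    stop_("case_fraction must be in (0, 1)")
  }
  if (!is.numeric(cfg$snp_effect_sd) || cfg$snp_effect_sd < 0) {
    stop_("snp_effect_sd must be non-negative")
  }
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd < 0) {
    stop_("noise_sd must be non-negative")
  }
  ce <- cfg$crf_effects
  if (!is.numeric(ce) || length(ce) != 4L ||
      !setequal(names(ce), c("gender", "age", "height", "weight"))) {
    stop_("crf_effects must be a named numeric: gender, age, height, weight")
  }
  invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
  cat("SimulationConfig (", x$sample, " design): ", x$n_subjects,
      " subjects, ", x$n_genes, " genes x ", x$snps_per_gene,
      " SNPs, tau = ", x$transfer_tau, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
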