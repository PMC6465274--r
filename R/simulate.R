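snp_ids_for <- function(cfg) {
  as.vector(vapply(seq_len(cfg$n_genes), function(g) {
    sprintf("gene%03d_snp%02d", g, seq_len(cfg$snps_per_gene))
  }, character(cfg$snps_per_gene)))
}

gene_map_for <- function(cfg) {
  ids <- snp_ids_for(cfg)
  split(ids, rep(sprintf("gene%03d", seq_len(cfg$n_genes)),
                 each = cfg$snps_per_gene))
}

# One haplotype layer of the Gaussian copula: within a gene, alleles share
# a latent factor with correlation ld_rho; thresholding the latent normal
# at qnorm(MAF) keeps each SNP marginally Bernoulli(MAF), so the dosage
# (sum of two layers) is Hardy-Weinberg at the drawn MAF.
draw_hap_block <- function(n, maf, rho) {
  k <- length(maf)
  shared <- rnorm(n)
  z <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  sweep(z, 2L, qnorm(maf), `<`) * 1L
}

draw_maf <- function(cfg) {
  m <- cfg$n_genes * cfg$snps_per_gene
  runif(m, cfg$maf_range[1], cfg$maf_range[2])
}

draw_genotypes <- function(cfg, n, maf = draw_maf(cfg)) {
  m <- cfg$n_genes * cfg$snps_per_gene
  dos <- matrix(0L, n, m)
  for (g in seq_len(cfg$n_genes)) {
    cols <- (g - 1L) * cfg$snps_per_gene + seq_len(cfg$snps_per_gene)
    dos[, cols] <- draw_hap_block(n, maf[cols], cfg$ld_rho) +
      draw_hap_block(n, maf[cols], cfg$ld_rho)
  }
  list(dosage = dos, maf = maf)
}

finish_genotypes <- function(cfg, dosage, subject_ids) {
  ids <- snp_ids_for(cfg)
  meta <- data.frame(
    snp_id = ids,
    chrom = as.character(rep(seq_len(cfg$n_genes), each = cfg$snps_per_gene)),
    pos = as.integer(seq_along(ids) * 1000L),
    effect_allele = "A", other_allele = "G",
    stringsAsFactors = FALSE
  )
  dimnames(dosage) <- list(subject_ids, ids)
  genotype_matrix(dosage, snp_meta = meta)
}

#' Simulate an LD-blocked genotype matrix
#'
#' Draws dosages gene by gene from a Gaussian copula: two independent
#' haplotype layers, each with exchangeable latent correlation `ld_rho`
#' within a gene, thresholded at the Hardy-Weinberg quantile of a MAF
#' drawn uniformly from `maf_range`. Marginal genotype frequencies are
#' Hardy-Weinberg; LD strength is controlled by the single `ld_rho`
#' parameter; different genes are independent.
#'
#' @param config A [simulation_config()] object.
#' @return A [genotype_matrix()] of `config$n_subjects` rows.
#' @export
#' @examples
#' g <- simulate_genotypes(simulation_config("bmd", n_subjects = 50, seed = 1))
#' table(g$dosage[, 1])
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed_(derive_seed(config$seed, "genotypes"), {
    d <- draw_genotypes(config, config$n_subjects)
    finish_genotypes(config, d$dosage,
                     sprintf("S%05d", seq_len(config$n_subjects)))
  })
}

# Causal architecture: round(frac_causal * m) SNPs chosen uniformly,
# effects Normal(0, snp_effect_sd), then attenuated by transfer_tau.
draw_effects <- function(cfg) {
  m <- cfg$n_genes * cfg$snps_per_gene
  n_causal <- round(cfg$frac_causal * m)
  beta <- numeric(m)
  if (n_causal > 0) {
    idx <- sample.int(m, n_causal)
    beta[idx] <- rnorm(n_causal, 0, cfg$snp_effect_sd)
  }
  beta * cfg$transfer_tau
}

# normal draw truncated below at `lower` by redraw (CRFs must stay
# positive; the truncation mass is < 0.5% so means/SDs are preserved)
rnorm_pos <- function(n, mean, sd, lower = 1) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= lower)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

draw_crfs <- function(cfg, n) {
  gender <- rbinom(n, 1L, 0.5) # 1 = female
  half <- cfg$gender_shift / 2
  age <- rnorm_pos(n, cfg$crf_means[["age"]], cfg$crf_sds[["age"]])
  height <- rnorm_pos(n, cfg$crf_means[["height"]] +
                        ifelse(gender == 1L, -half[["height"]],
                               half[["height"]]),
                      cfg$crf_sds[["height"]])
  weight <- rnorm_pos(n, cfg$crf_means[["weight"]] +
                        ifelse(gender == 1L, -half[["weight"]],
                               half[["weight"]]),
                      cfg$crf_sds[["weight"]])
  data.frame(gender = gender, age = age, height = height, weight = weight)
}

# CRF contribution centered at the population means (gender at 0.5), so
# `intercept` / `base_logodds` are the trait mean / baseline log-odds at
# mean covariates; regression slopes are unaffected by the centering
crf_lin <- function(cfg, crfs) {
  ce <- cfg$crf_effects
  ce[["gender"]] * (crfs$gender - 0.5) +
    ce[["age"]] * (crfs$age - cfg$crf_means[["age"]]) +
    ce[["height"]] * (crfs$height - cfg$crf_means[["height"]]) +
    ce[["weight"]] * (crfs$weight - cfg$crf_means[["weight"]])
}

# genetic contribution centered at the expected dosage 2*MAF
genetic_lin <- function(dosage, beta, maf) {
  drop(sweep(dosage, 2L, 2 * maf) %*% beta)
}

#' Simulate a quantitative (BMD) cohort
#'
#' Generates a population sample with femoral-neck BMD as the primary
#' trait: `fn_bmd = intercept + sum_j beta_j g_ij + gamma . CRFs +
#' Normal(0, noise_sd)`, where the per-SNP effects `beta` follow the
#' causal architecture of the config (fraction `frac_causal` nonzero,
#' scale `snp_effect_sd`, attenuated by `transfer_tau`). A companion
#' lumbar-spine BMD sharing the genetic and CRF signal is emitted with
#' correlation about `ls_bmd_cor`.
#'
#' @param config A [simulation_config()] (typically `sample = "bmd"`).
#' @return A `Cohort`: genotypes, phenotypes (with `fn_bmd`, `ls_bmd`),
#'   the realized `true_effects`, and the gene map.
#' @export
#' @examples
#' co <- simulate_quantitative_cohort(
#'   simulation_config("bmd", n_subjects = 100, seed = 3))
#' mean(co$phenotypes$fn_bmd)
simulate_quantitative_cohort <- function(config) {
  validate_sim_config(config)
  with_seed_(derive_seed(config$seed, "quantitative"), {
    n <- config$n_subjects
    gd <- draw_genotypes(config, n)
    beta <- draw_effects(config)
    crfs <- draw_crfs(config, n)
    genetic <- genetic_lin(gd$dosage, beta, gd$maf)
    mu <- config$intercept + genetic + crf_lin(config, crfs)
    fn_bmd <- mu + rnorm(n, 0, config$noise_sd)
    # LS-BMD: same systematic signal, fresh residual mixed to hit the
    # target residual correlation with FN-BMD
    r <- config$ls_bmd_cor
    ls_res <- r * (fn_bmd - mu) +
      sqrt(max(0, 1 - r^2)) * rnorm(n, 0, config$noise_sd)
    ls_bmd <- 0.948 - 0.920 + mu + ls_res
    subject_ids <- sprintf("S%05d", seq_len(n))
    geno <- finish_genotypes(config, gd$dosage, subject_ids)
    pheno <- data.frame(subject_id = subject_ids, crfs,
                        fn_bmd = fn_bmd, ls_bmd = ls_bmd,
                        stringsAsFactors = FALSE)
    new_cohort(geno, pheno, beta, gene_map_for(config))
  })
}

#' Simulate a case-control (fracture) cohort
#'
#' Draws subjects from a population logistic liability model,
#' `logit P(fracture) = base_logodds + sum_j beta_j g_ij + gamma . CRFs`
#' (effects attenuated by `transfer_tau`), then keeps exactly
#' `round(n_subjects * case_fraction)` cases and the complementary number
#' of controls by rejection sampling, emulating a designed case-control
#' study. Sampling is capped at 1000 draws per case-quota unit; an
#' unattainable prevalence raises an error.
#'
#' @param config A [simulation_config()] (typically `sample = "fracture"`).
#' @return A `Cohort` with a binary `fracture` phenotype; cases first.
#' @export
#' @examples
#' co <- simulate_casecontrol_cohort(
#'   simulation_config("fracture", n_subjects = 60, seed = 5))
#' table(co$phenotypes$fracture)
simulate_casecontrol_cohort <- function(config) {
  validate_sim_config(config)
  with_seed_(derive_seed(config$seed, "casecontrol"), {
    n <- config$n_subjects
    n_cases <- round(n * config$case_fraction)
    n_controls <- n - n_cases
    if (n_cases < 1L || n_controls < 1L) {
      stop_("case_fraction leaves no cases or no controls")
    }
    beta <- draw_effects(config)
    maf <- draw_maf(config)
    max_draws <- 1000 * n_cases
    batch <- max(1000L, 2L * n)
    case_g <- list(); case_c <- list()
    ctrl_g <- list(); ctrl_c <- list()
    got_cases <- 0L; got_ctrls <- 0L; drawn <- 0L
    while ((got_cases < n_cases || got_ctrls < n_controls) &&
           drawn < max_draws) {
      gd <- draw_genotypes(config, batch, maf)
      crfs <- draw_crfs(config, batch)
      eta <- config$base_logodds + genetic_lin(gd$dosage, beta, gd$maf) +
        crf_lin(config, crfs)
      y <- rbinom(batch, 1L, plogis(eta))
      drawn <- drawn + batch
      if (got_cases < n_cases) {
        take <- which(y == 1L)[seq_len(min(sum(y == 1L),
                                           n_cases - got_cases))]
        if (length(take)) {
          case_g[[length(case_g) + 1L]] <- gd$dosage[take, , drop = FALSE]
          case_c[[length(case_c) + 1L]] <- crfs[take, , drop = FALSE]
          got_cases <- got_cases + length(take)
        }
      }
      if (got_ctrls < n_controls) {
        take <- which(y == 0L)[seq_len(min(sum(y == 0L),
                                           n_controls - got_ctrls))]
        if (length(take)) {
          ctrl_g[[length(ctrl_g) + 1L]] <- gd$dosage[take, , drop = FALSE]
          ctrl_c[[length(ctrl_c) + 1L]] <- crfs[take, , drop = FALSE]
          got_ctrls <- got_ctrls + length(take)
        }
      }
    }
    if (got_cases < n_cases || got_ctrls < n_controls) {
      stop_("case-control generation failed: liability model yielded ",
            got_cases, "/", n_cases, " cases and ", got_ctrls, "/",
            n_controls, " controls within ", max_draws, " draws")
    }
    dosage <- rbind(do.call(rbind, case_g), do.call(rbind, ctrl_g))
    crfs <- rbind(do.call(rbind, case_c), do.call(rbind, ctrl_c))
    subject_ids <- sprintf("S%05d", seq_len(n))
    geno <- finish_genotypes(config, dosage, subject_ids)
    pheno <- data.frame(subject_id = subject_ids, crfs,
                        fracture = rep(c(1L, 0L), c(n_cases, n_controls)),
                        stringsAsFactors = FALSE)
    new_cohort(geno, pheno, beta, gene_map_for(config))
  })
}
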