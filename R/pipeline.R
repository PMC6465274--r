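#' Experiment configuration
#'
#' Assembles and validates the settings of one end-to-end experiment:
#' either the case-control fracture analysis (logistic models I-I, I-II,
#' I-III with AUC + reclassification/NRI evaluation) or the quantitative
#' BMD analysis (linear models II-I, II-II, II-III with paired MSE
#' comparison).
#'
#' @param experiment `"fracture"` or `"bmd"`.
#' @param simulation Either a [simulation_config()] or a named list of
#'   its arguments (a simulation block); mutually exclusive with
#'   `genotypes_path`/`phenotypes_path`.
#' @param genotypes_path,phenotypes_path,gene_map_path Input files when
#'   not simulating (dosage-table/VCF, phenotype TSV, gene-map TSV).
#' @param genotype_format Format for `genotypes_path`.
#' @param models Model ids to run; defaults to the experiment's three.
#' @param grs_snps Optional named list, model id -> SNP ids for that
#'   model's GRS panel.
#' @param select_genes_stage If `TRUE`, run the gene-based (GATES)
#'   selection stage and restrict GRS panels to selected genes.
#' @param summary_stats_path Optional per-SNP p-values for the selection
#'   stage; if absent, marginal p-values are computed from the cohort.
#' @param gene_threshold Gene-selection threshold (default `2e-6`).
#' @param cv_folds Outer fold count (default 10).
#' @param risk_cutoffs Risk-group cutoffs (default `c(0.10, 0.15)`).
#' @param outcome Outcome column override (e.g. `"ls_bmd"`).
#' @param seed Top-level seed.
#' @param output_dir Report directory.
#' @return A validated list of class `ExperimentConfig`.
#' @export
experiment_config <- function(experiment = c("fracture", "bmd"),
                              simulation = NULL,
                              genotypes_path = NULL,
                              phenotypes_path = NULL,
                              gene_map_path = NULL,
                              genotype_format = "dosage-table",
                              models = NULL,
                              grs_snps = NULL,
                              select_genes_stage = FALSE,
                              summary_stats_path = NULL,
                              gene_threshold = 2e-6,
                              cv_folds = 10L,
                              risk_cutoffs = c(0.10, 0.15),
                              outcome = NULL,
                              seed = 1L,
                              output_dir = tempfile("osteogrs_report_")) {
  experiment <- match.arg(experiment)
  models <- models %||% if (experiment == "fracture") {
    c("I-I", "I-II", "I-III")
  } else {
    c("II-I", "II-II", "II-III")
  }
  if (cv_folds < 2L) stop_("cv_folds must be >= 2")
  if (length(risk_cutoffs) != 2L || risk_cutoffs[1] >= risk_cutoffs[2] ||
      risk_cutoffs[1] <= 0 || risk_cutoffs[2] >= 1) {
    stop_("risk_cutoffs must be strictly increasing within (0, 1)")
  }
  if (is.null(simulation) &&
      (is.null(genotypes_path) || is.null(phenotypes_path))) {
    stop_("either a simulation block or genotype+phenotype paths required")
  }
  if (!is.null(simulation) && !inherits(simulation, "SimulationConfig")) {
    sample_kind <- if (experiment == "fracture") "fracture" else "bmd"
    simulation <- do.call(simulation_config,
                          c(list(sample = sample_kind), simulation))
  }
  structure(
    list(experiment = experiment, simulation = simulation,
         genotypes_path = genotypes_path, phenotypes_path = phenotypes_path,
         gene_map_path = gene_map_path, genotype_format = genotype_format,
         models = models, grs_snps = grs_snps,
         select_genes_stage = isTRUE(select_genes_stage),
         summary_stats_path = summary_stats_path,
         gene_threshold = gene_threshold, cv_folds = as.integer(cv_folds),
         risk_cutoffs = risk_cutoffs, outcome = outcome,
         seed = as.integer(seed), output_dir = output_dir),
    class = "ExperimentConfig"
  )
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; a `simulation`
#' mapping is passed through as the simulation block.
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @param output_dir Optional output-directory override.
#' @return An `ExperimentConfig`.
#' @export
read_experiment_config <- function(path, seed = NULL, output_dir = NULL) {
  if (!file.exists(path)) stop_(path, ": file does not exist")
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- seed
  if (!is.null(output_dir)) raw$output_dir <- output_dir
  if (!is.null(raw$risk_cutoffs)) raw$risk_cutoffs <- unlist(raw$risk_cutoffs)
  do.call(experiment_config, raw)
}

load_or_simulate <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- derive_seed(config$seed, "simulation")
    if (config$experiment == "fracture") {
      simulate_casecontrol_cohort(sim)
    } else {
      simulate_quantitative_cohort(sim)
    }
  } else {
    geno <- read_genotypes(config$genotypes_path, config$genotype_format)
    pheno <- read_phenotypes(config$phenotypes_path)
    if (!identical(geno$subject_ids, pheno$subject_id)) {
      common <- intersect(geno$subject_ids, pheno$subject_id)
      if (!length(common)) stop_("no common subjects between inputs")
      geno <- genotype_matrix(geno$dosage[common, , drop = FALSE],
                              snp_meta = geno$snp_meta)
      pheno <- pheno[match(common, pheno$subject_id), , drop = FALSE]
    }
    gene_map <- if (!is.null(config$gene_map_path)) {
      read_gene_map(config$gene_map_path)
    } else {
      list(all = geno$snp_ids)
    }
    new_cohort(geno, pheno, setNames(rep(NA_real_, length(geno$snp_ids)),
                                     geno$snp_ids), gene_map)
  }
}

# Gene-selection stage: GATES over the cohort's gene map, restricting the
# default GRS panel to SNPs in genes below the threshold. Falls back to
# all SNPs (with a log note) when nothing passes.
run_gene_selection <- function(config, cohort, outcome_col) {
  snp_ps <- if (!is.null(config$summary_stats_path)) {
    read_summary_stats(config$summary_stats_path)
  } else {
    family <- if (config$experiment == "fracture") "binomial" else "gaussian"
    marginal_snp_pvalues(cohort$genotypes,
                         cohort$phenotypes[[outcome_col]], family)
  }
  results <- gates_scan(cohort$gene_map, snp_ps, cohort$genotypes)
  selected <- select_genes(results, config$gene_threshold)
  snps <- unlist(cohort$gene_map[selected], use.names = FALSE)
  if (!length(snps)) {
    log_msg("gene selection: no gene below threshold ",
            config$gene_threshold, "; GRS panel keeps all SNPs")
    snps <- cohort$genotypes$snp_ids
  }
  list(results = results, selected = selected, snps = snps)
}

write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a full experiment from config to report bundle
#'
#' Stages: simulate or load the cohort; optional gene-based SNP-set
#' selection; k-fold cross-validation of the configured models (paired
#' fold assignments); evaluation — AUC, odds ratios, relative
#' importance, reclassification/NRI with Z-test for the fracture
#' experiment; paired MSE comparisons for the BMD experiment — and a
#' deterministic report bundle under `output_dir` (tables as TSV plus a
#' human-readable `report.txt`, the resolved config with its MD5 hash,
#' and the seed). Re-running an identical config produces bit-identical
#' report files.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, a list with the cohort, CV runs, evaluation
#'   objects and output paths.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  cohort <- stage("input", load_or_simulate(config))
  base_spec <- model_spec(config$models[[1L]])
  outcome_col <- config$outcome %||% base_spec$outcome
  selection <- NULL
  grs_snps <- config$grs_snps
  if (config$select_genes_stage) {
    selection <- stage("gene-selection",
                       run_gene_selection(config, cohort, outcome_col))
    grs_with <- config$models[vapply(config$models, function(m) {
      "GRS" %in% model_spec(m)$terms
    }, logical(1))]
    default_panel <- setNames(rep(list(selection$snps), length(grs_with)),
                              grs_with)
    grs_snps <- modifyList(default_panel, grs_snps %||% list())
  }
  cv <- stage("cross-validation",
              cross_validate(cohort, config$models, seed = config$seed,
                             nfolds = config$cv_folds, grs_snps = grs_snps,
                             outcome = outcome_col))
  files <- character()
  lines <- c(paste0("osteogrs experiment: ", config$experiment),
             paste0("models: ", paste(config$models, collapse = ", ")),
             paste0("n subjects: ", nrow(cohort$phenotypes)),
             paste0("cv folds: ", config$cv_folds),
             paste0("seed: ", config$seed), "")
  evaluation <- list()

  if (!is.null(selection)) {
    gene_path <- file.path(config$output_dir, "gene_results.tsv")
    write_gene_results(selection$results, gene_path, config$gene_threshold)
    files["gene_results"] <- gene_path
    lines <- c(lines, paste0("gene selection: ", length(selection$selected),
                             " gene(s) below ", config$gene_threshold), "")
  }

  # per-subject out-of-fold predictions, one column per model
  oof <- data.frame(subject_id = cohort$phenotypes$subject_id,
                    outcome = cohort$phenotypes[[outcome_col]],
                    stringsAsFactors = FALSE)
  for (m in config$models) oof[[m]] <- unname(cv[[m]]$oof_prediction)
  files["oof"] <- write_tsv(oof, file.path(config$output_dir,
                                           "oof_predictions.tsv"))

  if (base_spec$family == "binomial") {
    y <- cohort$phenotypes[[outcome_col]]
    auc_tab <- data.frame(
      model = config$models,
      auc = vapply(config$models,
                   function(m) auc(cv[[m]]$oof_prediction, y), numeric(1)),
      stringsAsFactors = FALSE
    )
    auc_tab$improvement_over_first <- auc_tab$auc - auc_tab$auc[1L]
    evaluation$auc <- auc_tab
    files["auc"] <- write_tsv(auc_tab, file.path(config$output_dir,
                                                 "auc.tsv"))
    lines <- c(lines, "AUC (pooled out-of-fold predictions):",
               sprintf("  %-6s %.4f (%+.4f vs %s)", auc_tab$model,
                       auc_tab$auc, auc_tab$improvement_over_first,
                       auc_tab$model[1L]), "")

    # full-sample descriptive fits: odds ratios and relative importance
    or_rows <- list()
    ri_rows <- list()
    for (m in config$models) {
      needs_grs <- "GRS" %in% model_spec(m)$terms
      grs_full <- NULL
      if (needs_grs) {
        snp_set <- grs_snps[[m]] %||% cohort$genotypes$snp_ids
        gm_full <- train_grs(
          cohort$genotypes$dosage[, snp_set, drop = FALSE], y, "fracture",
          seed = derive_seed(config$seed, paste0(m, "-full")))
        grs_full <- compute_grs(
          apply_orientation(cohort$genotypes$dosage[, snp_set, drop = FALSE],
                            gm_full$orientation), gm_full)
      }
      fit <- if (needs_grs && var(grs_full) == 0) {
        fit_drop_grs(cohort$phenotypes, m, outcome_col)
      } else {
        fit_model(cohort$phenotypes, m, grs = grs_full,
                  outcome = outcome_col)
      }
      ors <- odds_ratios(fit)
      ors$model <- m
      or_rows[[m]] <- ors
      ri <- relative_importance(fit, cohort$phenotypes, grs = grs_full)
      ri_rows[[m]] <- data.frame(model = m, term = names(ri),
                                 share_pct = 100 * as.numeric(ri),
                                 total_pct = 100 * attr(ri, "total"),
                                 stringsAsFactors = FALSE)
    }
    evaluation$odds_ratios <- do.call(rbind, or_rows)
    evaluation$relative_importance <- do.call(rbind, ri_rows)
    rownames(evaluation$odds_ratios) <- NULL
    rownames(evaluation$relative_importance) <- NULL
    files["odds_ratios"] <- write_tsv(
      evaluation$odds_ratios, file.path(config$output_dir, "odds_ratios.tsv"))
    files["relative_importance"] <- write_tsv(
      evaluation$relative_importance,
      file.path(config$output_dir, "relative_importance.tsv"))

    # reclassification of each augmented model against the baseline
    baseline <- config$models[1L]
    nri_rows <- list()
    for (m in config$models[-1L]) {
      rec <- reclassification_table(cv[[baseline]]$oof_prediction,
                                    cv[[m]]$oof_prediction, y,
                                    cutoffs = config$risk_cutoffs)
      nri <- nri_ztest(compute_nri(rec))
      evaluation$reclassification[[m]] <- rec
      evaluation$nri[[m]] <- nri
      tab_path <- file.path(config$output_dir,
                            paste0("reclassification_", m, "_vs_",
                                   baseline, ".tsv"))
      both <- rbind(
        data.frame(group = "event", baseline_category = rownames(rec$table_event),
                   rec$table_event, check.names = FALSE),
        data.frame(group = "nonevent",
                   baseline_category = rownames(rec$table_nonevent),
                   rec$table_nonevent, check.names = FALSE)
      )
      files[paste0("reclass_", m)] <- write_tsv(both, tab_path)
      nri_rows[[m]] <- data.frame(
        comparison = paste(m, "vs", baseline),
        nri_exact = nri$nri, nri_exact_pct = 100 * nri$nri,
        nri_printed_pct = combine_printed_components(
          percent_printed(nri$p_up_event), percent_printed(nri$p_down_event),
          percent_printed(nri$p_down_nonevent),
          percent_printed(nri$p_up_nonevent)),
        z = nri$z, p_value = nri$p_value, stringsAsFactors = FALSE
      )
      lines <- c(lines,
                 paste0("Reclassification ", m, " vs ", baseline, ":"),
                 sprintf("  events:     up %d (%.2f%%), down %d (%.2f%%) of %d",
                         nri$up_event, percent_printed(nri$p_up_event),
                         nri$down_event, percent_printed(nri$p_down_event),
                         nri$n_event),
                 sprintf("  non-events: up %d (%.2f%%), down %d (%.2f%%) of %d",
                         nri$up_nonevent, percent_printed(nri$p_up_nonevent),
                         nri$down_nonevent, percent_printed(nri$p_down_nonevent),
                         nri$n_nonevent),
                 sprintf("  NRI = %.4f%% (exact), Z = %.3f, p = %.3f",
                         100 * nri$nri, nri$z, nri$p_value), "")
    }
    evaluation$nri_table <- do.call(rbind, nri_rows)
    rownames(evaluation$nri_table) <- NULL
    files["nri"] <- write_tsv(evaluation$nri_table,
                              file.path(config$output_dir, "nri.tsv"))
  } else {
    # BMD experiment: paired MSE comparisons over all model pairs
    pairs <- utils::combn(config$models, 2L, simplify = FALSE)
    mse_rows <- lapply(pairs, function(pr) {
      cmp <- mse_compare(cv[[pr[1]]], cv[[pr[2]]])
      data.frame(model_a = pr[1], model_b = pr[2],
                 mse_a = mean(cmp$mse_a), mse_b = mean(cmp$mse_b),
                 mean_diff = cmp$mean_diff, t = cmp$t,
                 p_value = cmp$p_value, stringsAsFactors = FALSE)
    })
    evaluation$mse <- do.call(rbind, mse_rows)
    files["mse"] <- write_tsv(evaluation$mse,
                              file.path(config$output_dir,
                                        "mse_comparisons.tsv"))
    lines <- c(lines, "Paired MSE comparisons (10-fold test error):",
               sprintf("  %-6s vs %-6s: MSE %.5g vs %.5g, t = %.3f, p = %.4g",
                       evaluation$mse$model_a, evaluation$mse$model_b,
                       evaluation$mse$mse_a, evaluation$mse$mse_b,
                       evaluation$mse$t, evaluation$mse$p_value), "")
  }

  # provenance: resolved config + hash + seed
  cfg_path <- file.path(config$output_dir, "resolved_config.yaml")
  dump <- unclass(config)
  dump$output_dir <- NULL # location, not analysis configuration
  if (!is.null(config$simulation)) {
    dump$simulation <- unclass(config$simulation)
  }
  yaml::write_yaml(dump, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  lines <- c(lines, paste0("config md5: ", cfg_hash))
  report_path <- file.path(config$output_dir, "report.txt")
  writeLines(lines, report_path)
  files["report"] <- report_path
  files["config"] <- cfg_path
  log_msg("report written to ", config$output_dir)
  invisible(list(config = config, cohort = cohort, cv = cv,
                 selection = selection, evaluation = evaluation,
                 files = files, config_hash = cfg_hash))
}

#' Verify printed reclassification tables
#'
#' Recomputes the NRI components, exact and printed-style percentages,
#' Z statistic and p-value from a pair of 3x3 reclassification count
#' tables, optionally comparing against expected values within a
#' tolerance.
#'
#' @param table_event,table_nonevent 3x3 count matrices (rows = baseline
#'   category lower/middle/higher, columns = augmented category).
#' @param expected Optional named list of expected values among
#'   `up_event_pct`, `down_event_pct`, `up_nonevent_pct`,
#'   `down_nonevent_pct`, `event_net_pct`, `nonevent_net_pct`,
#'   `nri_exact_pct`, `z`, `p_value`.
#' @param tolerance Absolute comparison tolerance (default 0.005 on
#'   percentages rounded to two decimals).
#' @return List with the recomputed quantities and, when `expected` is
#'   given, a logical `pass` vector per check.
#' @export
verify_tables <- function(table_event, table_nonevent, expected = NULL,
                          tolerance = 0.005) {
  rec <- reclassification_from_counts(table_event, table_nonevent)
  nri <- nri_ztest(compute_nri(rec))
  computed <- list(
    up_event_pct = percent_printed(nri$p_up_event),
    down_event_pct = percent_printed(nri$p_down_event),
    up_nonevent_pct = percent_printed(nri$p_up_nonevent),
    down_nonevent_pct = percent_printed(nri$p_down_nonevent),
    event_net_pct = percent_printed(nri$p_up_event - nri$p_down_event),
    nonevent_net_pct = percent_printed(nri$p_down_nonevent -
                                         nri$p_up_nonevent),
    nri_exact = nri$nri, nri_exact_pct = 100 * nri$nri,
    z = nri$z, p_value = nri$p_value
  )
  out <- list(nri = nri, computed = computed)
  if (!is.null(expected)) {
    unknown <- setdiff(names(expected), names(computed))
    if (length(unknown)) {
      stop_("unknown expected value name(s): ",
            paste(unknown, collapse = ", "))
    }
    out$pass <- vapply(names(expected), function(k) {
      abs(computed[[k]] - expected[[k]]) <= tolerance
    }, logical(1))
  }
  out
}
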