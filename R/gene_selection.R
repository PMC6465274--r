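#' Pairwise LD (dosage correlation) for a set of SNPs
#'
#' Pearson correlation of dosage vectors, the LD input to the extended
#' Simes gene test. Monomorphic SNPs have no defined correlation and are
#' rejected by name.
#'
#' @param genotypes A [genotype_matrix()] (the analysis cohort's own
#'   genotypes serve as the LD panel).
#' @param snp_ids SNP ids to correlate (must exist in `genotypes`).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
ld_correlation <- function(genotypes, snp_ids) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  if (length(snp_ids) < 1L) stop_("at least one SNP id is required")
  missing <- setdiff(snp_ids, genotypes$snp_ids)
  if (length(missing)) {
    stop_("SNP id(s) not in genotype matrix: ", paste(missing, collapse = ", "))
  }
  x <- genotypes$dosage[, snp_ids, drop = FALSE]
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop_("monomorphic SNP(s): ", paste(snp_ids[sds == 0], collapse = ", "))
  }
  r <- cor(x)
  diag(r) <- 1
  r
}

#' Effective number of independent tests
#'
#' Eigenvalue-based count for a set of correlated tests:
#' `m_e = m - sum_{lambda_i > 1} (lambda_i - 1)`, where `lambda_i` are the
#' eigenvalues of the p-value correlation matrix. Equal to `m` for
#' independent tests and 1 for perfectly correlated ones; clamped to
#' `[1, m]` against numerical noise.
#'
#' @param p_correlation Symmetric correlation matrix of the test p-values.
#' @return The effective test count, a scalar in `[1, m]`.
#' @export
#' @examples
#' effective_tests(diag(4)) # 4 independent tests
effective_tests <- function(p_correlation) {
  if (!is.matrix(p_correlation) ||
      nrow(p_correlation) != ncol(p_correlation)) {
    stop_("p_correlation must be a square matrix")
  }
  if (!isSymmetric(unname(p_correlation), tol = 1e-8)) {
    stop_("p_correlation must be symmetric")
  }
  m <- nrow(p_correlation)
  lam <- eigen(p_correlation, symmetric = TRUE, only.values = TRUE)$values
  me <- m - sum(pmax(lam - 1, 0))
  min(max(me, 1), m)
}

# Correlation between two SNPs' association p-values, approximated from
# the dosage correlation r by a sixth-degree polynomial in |r| (the
# canonical extended-Simes approximation). |r| = 1 means identical tests,
# hence identical p-values: snapped to exactly 1.
p_value_correlation <- function(ld) {
  a <- abs(ld)
  rho <- 0.2982 * a^6 - 0.0127 * a^5 + 0.0588 * a^4 +
    0.0099 * a^3 + 0.6281 * a^2 - 0.0009 * a
  rho[a >= 1 - 1e-12] <- 1
  rho <- pmin(pmax(rho, 0), 1)
  diag(rho) <- 1
  rho
}

#' Gene-based association p-value by the extended Simes procedure (GATES)
#'
#' Combines a gene's per-SNP p-values into one gene-level p-value:
#' with SNP p-values sorted ascending, `p_(1) <= ... <= p_(m)`,
#' `gene_p = min_j m_e p_(j) / m_e(j)`, where `m_e` is the effective
#' number of tests over all `m` SNPs and `m_e(j)` over the `j` most
#' significant SNPs, both computed from the LD-derived p-value
#' correlation matrix (see [effective_tests()]). With independent SNPs
#' this reduces to the Simes combination; with perfectly correlated SNPs
#' it returns the minimum p-value unpenalised.
#'
#' @param snp_ps Named numeric vector of per-SNP p-values in `(0, 1]`,
#'   restricted to one gene.
#' @param ld SNP-by-SNP dosage correlation matrix aligned with `snp_ps`
#'   (same ids, any order if dimnames are present).
#' @param gene_id Optional gene label carried into the result.
#' @return A list of class `GeneTestResult`: `gene_id`, `m`, `me_total`,
#'   `gene_p`, `snp_order` (ids by ascending p, ties broken by id).
#' @export
#' @examples
#' gates_gene_p(c(a = 0.01, b = 0.02, c = 0.03, d = 0.04), diag(4))
gates_gene_p <- function(snp_ps, ld, gene_id = NA_character_) {
  if (length(snp_ps) == 0L) stop_("empty gene: no SNP p-values")
  if (any(snp_ps <= 0 | snp_ps > 1)) stop_("p-values must be in (0, 1]")
  m <- length(snp_ps)
  if (!is.matrix(ld) || nrow(ld) != m || ncol(ld) != m) {
    stop_("ld must be an m x m matrix matching snp_ps")
  }
  ids <- names(snp_ps) %||% as.character(seq_len(m))
  if (!is.null(dimnames(ld)) && !is.null(rownames(ld))) {
    if (!setequal(rownames(ld), ids)) {
      stop_("ld dimnames do not match SNP ids")
    }
    ld <- ld[ids, ids, drop = FALSE]
  }
  ord <- order(snp_ps, ids) # ties broken by SNP id for determinism
  p_sorted <- snp_ps[ord]
  pcor <- p_value_correlation(ld)[ord, ord, drop = FALSE]
  me_total <- effective_tests(pcor)
  me_j <- vapply(seq_len(m), function(j) {
    effective_tests(pcor[seq_len(j), seq_len(j), drop = FALSE])
  }, numeric(1))
  gene_p <- min(1, min(me_total * p_sorted / me_j))
  structure(
    list(gene_id = gene_id, m = m, me_total = me_total, gene_p = gene_p,
         snp_order = ids[ord]),
    class = "GeneTestResult"
  )
}

#' @export
print.GeneTestResult <- function(x, ...) {
  cat("GeneTestResult", if (!is.na(x$gene_id)) paste0("(", x$gene_id, ")"),
      ": m =", x$m, ", m_e =", signif(x$me_total, 4),
      ", p =", signif(x$gene_p, 4), "\n")
  invisible(x)
}

#' Run the gene-based test over every gene in a map
#'
#' @param gene_map Named list `gene_id -> snp_ids` (see [read_gene_map()]).
#' @param snp_ps Named per-SNP p-values covering every mapped SNP.
#' @param genotypes LD panel, a [genotype_matrix()] containing all mapped
#'   SNPs.
#' @return A list of `GeneTestResult`, one per gene, in map order.
#' @export
gates_scan <- function(gene_map, snp_ps, genotypes) {
  missing <- setdiff(unlist(gene_map), names(snp_ps))
  if (length(missing)) {
    stop_("no p-value for mapped SNP(s): ",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  lapply(names(gene_map), function(g) {
    ids <- gene_map[[g]]
    gates_gene_p(snp_ps[ids], ld_correlation(genotypes, ids), gene_id = g)
  })
}

#' Select genes below a significance threshold
#'
#' Keeps genes whose combined p-value is strictly below `threshold`
#' (a gene at exactly the threshold is excluded), preserving input order.
#'
#' @param results List of `GeneTestResult` objects.
#' @param threshold Significance threshold in `(0, 1]`; default `2e-6`,
#'   the conventional gene-based genome-wide level.
#' @return Character vector of selected gene ids.
#' @export
select_genes <- function(results, threshold = 2e-6) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop_("threshold must be in (0, 1]")
  }
  ids <- vapply(results, function(r) r$gene_id, character(1))
  ps <- vapply(results, function(r) r$gene_p, numeric(1))
  ids[ps < threshold]
}

#' Write gene-based test results as a tab-delimited table
#'
#' @param results List of `GeneTestResult` objects.
#' @param path Output path.
#' @param threshold Selection threshold used for the `selected` flag.
#' @return The table, invisibly.
#' @export
write_gene_results <- function(results, path, threshold = 2e-6) {
  tab <- data.frame(
    gene_id = vapply(results, `[[`, character(1), "gene_id"),
    m = vapply(results, `[[`, numeric(1), "m"),
    me_total = vapply(results, `[[`, numeric(1), "me_total"),
    gene_p = vapply(results, `[[`, numeric(1), "gene_p"),
    stringsAsFactors = FALSE
  )
  tab$selected <- tab$gene_p < threshold
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Marginal per-SNP association p-values within a cohort
#'
#' Univariate score-type association of each SNP with the outcome:
#' Wald p from a one-predictor linear or logistic fit. Used when the
#' gene-selection stage runs on the analysis cohort itself rather than on
#' external summary statistics.
#'
#' @param genotypes A [genotype_matrix()].
#' @param outcome Numeric outcome vector (binary for `"binomial"`).
#' @param family `"gaussian"` or `"binomial"`.
#' @return Named p-value vector, one per SNP.
#' @export
marginal_snp_pvalues <- function(genotypes, outcome,
                                 family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  x <- genotypes$dosage
  if (length(outcome) != nrow(x)) stop_("outcome length mismatch")
  vapply(seq_len(ncol(x)), function(j) {
    g <- x[, j]
    if (sd(g) == 0) return(1)
    fit <- if (family == "gaussian") {
      summary(lm(outcome ~ g))$coefficients
    } else {
      summary(glm(outcome ~ g, family = binomial()))$coefficients
    }
    if (nrow(fit) < 2L) 1 else max(fit[2L, 4L], .Machine$double.xmin)
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(genotypes$snp_ids)
}
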