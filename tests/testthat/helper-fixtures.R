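options(osteogrs.verbose = 0)

# ---- independent oracles -------------------------------------------------

# Simes combined p-value, brute force
simes_p <- function(p) {
  m <- length(p)
  min(m * sort(p) / seq_len(m))
}

# AUC by exhaustive pair counting, ties counted one half
auc_paircount <- function(pred, y) {
  cases <- pred[y == 1]
  ctrls <- pred[y == 0]
  s <- 0
  for (a in cases) {
    for (b in ctrls) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(cases) * length(ctrls))
}

# reclassification cross-tabulation by explicit double loop
reclass_bruteforce <- function(p_base, p_aug, y, cutoffs = c(0.10, 0.15)) {
  grp <- function(p) {
    if (p < cutoffs[1]) 1L else if (p < cutoffs[2]) 2L else 3L
  }
  te <- matrix(0L, 3, 3)
  tn <- matrix(0L, 3, 3)
  for (i in seq_along(y)) {
    r <- grp(p_base[i]); c <- grp(p_aug[i])
    if (y[i] == 1) te[r, c] <- te[r, c] + 1L else tn[r, c] <- tn[r, c] + 1L
  }
  list(event = te, nonevent = tn)
}

# ---- printed reclassification tables (rows = baseline lower/middle/higher,
# columns = augmented), and their printed component percentages -----------

table5_event <- matrix(c(88, 0, 0,
                         0, 110, 0,
                         0, 4, 148), 3, 3, byrow = TRUE)
table5_nonevent <- matrix(c(76, 0, 0,
                            0, 102, 1,
                            1, 6, 164), 3, 3, byrow = TRUE)
table5_printed <- list(up_event = 0.00, down_event = 1.14,
                       up_nonevent = 0.30, down_nonevent = 2.00)

table6_event <- matrix(c(87, 1, 0,
                         0, 107, 3,
                         0, 4, 148), 3, 3, byrow = TRUE)
table6_nonevent <- matrix(c(75, 1, 0,
                            0, 103, 0,
                            0, 5, 166), 3, 3, byrow = TRUE)
table6_printed <- list(up_event = 1.14, down_event = 1.14,
                       up_nonevent = 0.30, down_nonevent = 1.43)

# ---- small fixture builders ---------------------------------------------

small_fracture_cohort <- function(seed = 11, n = 120, n_genes = 4,
                                  snps_per_gene = 4, ...) {
  simulate_casecontrol_cohort(simulation_config(
    "fracture", n_subjects = n, n_genes = n_genes,
    snps_per_gene = snps_per_gene, seed = seed, ...))
}

small_bmd_cohort <- function(seed = 12, n = 200, n_genes = 4,
                             snps_per_gene = 4, ...) {
  simulate_quantitative_cohort(simulation_config(
    "bmd", n_subjects = n, n_genes = n_genes,
    snps_per_gene = snps_per_gene, seed = seed, ...))
}

write_vcf_fixture <- function(path, gt_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "subj1\tsubj2"),
    gt_lines
  ), path)
  path
}
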