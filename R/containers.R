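#' Genotype dosage matrix
#'
#' Container for a subjects x SNPs additive-dosage matrix (counts of the
#' coded allele, values 0/1/2) with per-SNP metadata. Missing dosages are
#' not representable: readers and constructors reject them.
#'
#' @param dosage Integer-valued matrix, subjects in rows, SNPs in columns,
#'   entries in `{0, 1, 2}`. Row names are subject ids, column names SNP ids
#'   (or supply `subject_ids` / `snp_ids`).
#' @param subject_ids,snp_ids Optional character vectors overriding dimnames.
#' @param snp_meta Optional data.frame with one row per SNP and columns
#'   `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`.
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `dosage`, `subject_ids`, `snp_ids`, `snp_meta`.
#' @export
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("rs1", "rs2"))))
#' g$snp_ids
genotype_matrix <- function(dosage, subject_ids = NULL, snp_ids = NULL,
                            snp_meta = NULL) {
  if (!is.matrix(dosage)) stop_("`dosage` must be a matrix")
  if (nrow(dosage) == 0L || ncol(dosage) == 0L) {
    stop_("genotype matrix must have at least one subject and one SNP")
  }
  subject_ids <- subject_ids %||% rownames(dosage)
  snp_ids <- snp_ids %||% colnames(dosage)
  if (is.null(subject_ids) || is.null(snp_ids)) {
    stop_("subject and SNP ids are required (dimnames or arguments)")
  }
  subject_ids <- as.character(subject_ids)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(subject_ids)) stop_("duplicate subject ids")
  if (anyDuplicated(snp_ids)) stop_("duplicate SNP ids")
  if (length(subject_ids) != nrow(dosage) || length(snp_ids) != ncol(dosage)) {
    stop_("id lengths do not match dosage dimensions")
  }
  if (anyNA(dosage)) stop_("missing genotype dosage values are not allowed")
  if (!all(dosage %in% c(0, 1, 2))) {
    stop_("dosage values must be 0, 1 or 2")
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(subject_ids, snp_ids)
  if (is.null(snp_meta)) {
    snp_meta <- data.frame(
      snp_id = snp_ids, chrom = NA_character_, pos = NA_integer_,
      effect_allele = NA_character_, other_allele = NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
    miss <- setdiff(need, names(snp_meta))
    if (length(miss)) stop_("snp_meta missing columns: ",
                            paste(miss, collapse = ", "))
    if (!identical(as.character(snp_meta$snp_id), snp_ids)) {
      stop_("snp_meta$snp_id must match SNP ids in order")
    }
  }
  structure(
    list(dosage = dosage, subject_ids = subject_ids, snp_ids = snp_ids,
         snp_meta = snp_meta),
    class = "GenotypeMatrix"
  )
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$subject_ids), "subjects x",
      length(x$snp_ids), "SNPs\n")
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$dosage)

# Validate a phenotype table: required id column, CRFs, and at least one
# outcome among fracture / ls_bmd / fn_bmd. Returns the table unchanged.
validate_phenotypes <- function(pheno, file = "<phenotypes>") {
  if (!is.data.frame(pheno)) stop_("phenotypes must be a data.frame")
  need <- c("subject_id", "gender", "age", "height", "weight")
  miss <- setdiff(need, names(pheno))
  if (length(miss)) {
    stop_(file, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  outcomes <- intersect(c("fracture", "ls_bmd", "fn_bmd"), names(pheno))
  if (!length(outcomes)) {
    stop_(file, ": at least one of fracture, ls_bmd, fn_bmd is required")
  }
  if (anyDuplicated(pheno$subject_id)) {
    stop_(file, ": duplicate subject_id values")
  }
  for (col in c("age", "height", "weight")) {
    v <- pheno[[col]]
    if (!is.numeric(v)) stop_(file, ": column '", col, "' must be numeric")
    if (anyNA(v)) stop_(file, ": missing values in column '", col, "'")
    if (any(v <= 0)) {
      stop_(file, ": column '", col, "' must be strictly positive (row ",
            which(v <= 0)[1L], ")")
    }
  }
  if (!all(pheno$gender %in% c(0, 1))) {
    stop_(file, ": gender must be coded 0 (male) / 1 (female)")
  }
  if ("fracture" %in% names(pheno)) {
    if (anyNA(pheno$fracture) || !all(pheno$fracture %in% c(0, 1))) {
      stop_(file, ": fracture must be coded 0/1 without missing values")
    }
  }
  for (col in intersect(c("ls_bmd", "fn_bmd"), names(pheno))) {
    if (!is.numeric(pheno[[col]]) || anyNA(pheno[[col]])) {
      stop_(file, ": column '", col, "' must be numeric without missing values")
    }
  }
  pheno$subject_id <- as.character(pheno$subject_id)
  pheno
}

# A simulated cohort bundles genotypes, phenotypes, the generating per-SNP
# effects, and the gene -> SNP map used to lay out LD blocks.
new_cohort <- function(genotypes, phenotypes, true_effects, gene_map) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  phenotypes <- validate_phenotypes(phenotypes)
  if (!identical(genotypes$subject_ids, phenotypes$subject_id)) {
    stop_("genotypes and phenotypes must cover the same subjects in order")
  }
  if (length(true_effects) != length(genotypes$snp_ids)) {
    stop_("true_effects must have one entry per SNP")
  }
  names(true_effects) <- genotypes$snp_ids
  structure(
    list(genotypes = genotypes, phenotypes = phenotypes,
         true_effects = true_effects, gene_map = gene_map),
    class = "Cohort"
  )
}

#' @export
print.Cohort <- function(x, ...) {
  out <- intersect(c("fracture", "ls_bmd", "fn_bmd"), names(x$phenotypes))
  cat("Cohort:", nrow(x$phenotypes), "subjects,",
      length(x$genotypes$snp_ids), "SNPs in",
      length(x$gene_map), "genes; outcomes:",
      paste(out, collapse = ", "), "\n")
  invisible(x)
}
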