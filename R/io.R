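#' Read a genotype dosage matrix
#'
#' Two dialects are supported:
#' * `"dosage-table"`: tab-delimited, header row, first column
#'   `subject_id`, remaining columns one per SNP, integer cells in
#'   `{0, 1, 2}`. Lossless round-trip with [write_genotypes()].
#' * `"vcf"`: VCF 4.x via the vcfR parser; diploid `GT` fields are
#'   converted to alternate-allele counts. Only biallelic sites are
#'   accepted, and any missing call (`./.`) is an error — the pipeline
#'   assumes fully imputed input.
#'
#' @param path File path.
#' @param format `"vcf"` or `"dosage-table"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage-table", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_(path, ": file does not exist")
  if (format == "vcf") read_genotypes_vcf(path) else read_dosage_table(path)
}

read_dosage_table <- function(path) {
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character", comment.char = ""),
    error = function(e) stop_(path, ": parse error: ", conditionMessage(e))
  )
  if (ncol(tab) < 2L || names(tab)[1] != "subject_id") {
    stop_(path, ": first column must be 'subject_id' followed by SNP columns")
  }
  snp_ids <- names(tab)[-1]
  dos <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "numeric")
  bad <- which(is.na(dos) | !(dos %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_(path, ": line ", bad[1, 1] + 1L, ", field '", snp_ids[bad[1, 2]],
          "': dosage must be 0, 1 or 2")
  }
  genotype_matrix(dos, subject_ids = tab$subject_id, snp_ids = snp_ids)
}

read_genotypes_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop_(path, ": VCF parse error: ",
                                          conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop_(path, ": multi-allelic record at ", fix[which(multi)[1], "CHROM"],
          ":", fix[which(multi)[1], "POS"], " (only biallelic sites supported)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop_(path, ": no GT field in VCF")
  snp_ids <- fix[, "ID"]
  blank <- is.na(snp_ids) | snp_ids == "." | snp_ids == ""
  snp_ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  count_alt <- function(g, snp) {
    if (is.na(g) || grepl("\\.", g)) {
      stop_(path, ": missing genotype at SNP '", snp, "'")
    }
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || !all(alleles %in% c("0", "1"))) {
      stop_(path, ": unsupported GT '", g, "' at SNP '", snp, "'")
    }
    sum(alleles == "1")
  }
  dos <- matrix(0L, nrow = ncol(gt), ncol = nrow(gt))
  for (j in seq_len(nrow(gt))) {
    dos[, j] <- vapply(gt[j, ], count_alt, integer(1), snp = snp_ids[j])
  }
  meta <- data.frame(
    snp_id = snp_ids, chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    effect_allele = fix[, "ALT"], other_allele = fix[, "REF"],
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, subject_ids = colnames(gt), snp_ids = snp_ids,
                  snp_meta = meta)
}

#' Write a genotype matrix as a tab-delimited dosage table
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  tab <- data.frame(subject_id = genotypes$subject_ids,
                    genotypes$dosage, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_delim_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop_(path, ": file does not exist")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = sep, check.names = FALSE,
               stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) stop_(path, ": parse error: ", conditionMessage(e))
  )
  miss <- setdiff(required, names(tab))
  if (length(miss)) {
    stop_(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  for (col in intersect(numeric_cols, names(tab))) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (anyNA(v)) {
      line <- (if (length(bad)) bad[1] else which(is.na(v))[1]) + 1L
      stop_(path, ": line ", line, ", field '", col, "': non-numeric or ",
            "missing value")
    }
    tab[[col]] <- v
  }
  tab
}

#' Read a phenotype/covariate table
#'
#' Delimited text (TSV, or CSV by `.csv` extension) with header columns
#' `subject_id`, `gender` (0 = male, 1 = female), `age`, `height`,
#' `weight`, and at least one of `fracture` (0/1), `ls_bmd`, `fn_bmd`.
#' Values are validated (positive CRFs, no missingness); unknown columns
#' are preserved but unused.
#'
#' @param path File path.
#' @return A validated phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  tab <- read_delim_checked(
    path, c("subject_id", "gender", "age", "height", "weight"),
    numeric_cols = c("gender", "age", "height", "weight",
                     "fracture", "ls_bmd", "fn_bmd")
  )
  validate_phenotypes(tab, file = path)
}

#' Write a phenotype table
#' @param phenotypes A phenotype data.frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-SNP map
#'
#' Long-format delimited text with columns `gene_id` and `snp_id`. A gene
#' listed in several runs is merged with first-appearance order preserved
#' and duplicate SNPs collapsed; empty genes are impossible by
#' construction.
#'
#' @param path File path.
#' @return A named list: `gene_id -> character vector of snp_ids`, in
#'   first-appearance gene order.
#' @export
read_gene_map <- function(path) {
  tab <- read_delim_checked(path, c("gene_id", "snp_id"))
  if (nrow(tab) == 0L) stop_(path, ": empty gene map")
  genes <- unique(as.character(tab$gene_id))
  out <- lapply(genes, function(g) {
    unique(as.character(tab$snp_id[tab$gene_id == g]))
  })
  names(out) <- genes
  out
}

#' Write a gene map in long format
#' @param gene_map Named list of SNP id vectors.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gene_map, path) {
  tab <- data.frame(
    gene_id = rep(names(gene_map), lengths(gene_map)),
    snp_id = unlist(gene_map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP association summary statistics
#'
#' Tab-delimited with columns `snp_id` and `p`; p-values must lie in the
#' half-open interval (0, 1] (a p of exactly 0 is rejected), and SNP ids
#' must be unique.
#'
#' @param path File path.
#' @return A named numeric vector of p-values.
#' @export
read_summary_stats <- function(path) {
  tab <- read_delim_checked(path, c("snp_id", "p"), numeric_cols = "p")
  if (anyDuplicated(tab$snp_id)) {
    stop_(path, ": duplicate snp_id '",
          tab$snp_id[anyDuplicated(tab$snp_id)], "'")
  }
  bad <- which(tab$p <= 0 | tab$p > 1)
  if (length(bad)) {
    stop_(path, ": line ", bad[1] + 1L, ", field 'p': p-value must be in ",
          "(0, 1]")
  }
  setNames(tab$p, tab$snp_id)
}
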