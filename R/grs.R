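#' Orient SNP dosages toward the risk direction
#'
#' Each SNP is recoded so that its counted allele points toward higher
#' fracture risk (binary outcome) or lower BMD (quantitative outcome):
#' if the marginal association of the dosage with the outcome is
#' protective (fracture) or BMD-increasing (bmd), the dosage is flipped
#' to `2 - dosage`. The marginal association is the score-statistic sign,
#' i.e. the sign of `cov(dosage, outcome)` on the training rows; an
#' exactly zero association defaults to no flip. Flags are recorded so
#' the identical recoding can be applied to held-out data.
#'
#' @param dosage Subjects x SNPs dosage matrix (training rows only).
#' @param outcome Training outcome: 0/1 fracture or numeric BMD.
#' @param trait_kind `"fracture"` or `"bmd"`.
#' @return List with `flip` (named logical per SNP) and `dosage` (the
#'   reoriented matrix).
#' @export
orient_risk_alleles <- function(dosage, outcome,
                                trait_kind = c("fracture", "bmd")) {
  trait_kind <- match.arg(trait_kind)
  if (!is.matrix(dosage)) stop_("dosage must be a matrix")
  if (length(outcome) != nrow(dosage)) stop_("outcome length mismatch")
  if (sd(outcome) == 0) stop_("constant outcome: cannot orient risk alleles")
  assoc <- drop(cov(dosage, outcome))
  flip <- if (trait_kind == "fracture") assoc < 0 else assoc > 0
  names(flip) <- colnames(dosage)
  list(flip = flip, dosage = apply_orientation(dosage, flip))
}

#' Apply stored orientation flags to a dosage matrix
#'
#' Flipping is an involution: applying the same flags twice restores the
#' original dosages (`2 - (2 - x) = x`).
#'
#' @param dosage Subjects x SNPs dosage matrix.
#' @param flip Named logical vector over the matrix's SNP columns.
#' @return The reoriented matrix.
#' @export
apply_orientation <- function(dosage, flip) {
  if (!is.null(names(flip)) && !is.null(colnames(dosage))) {
    if (!setequal(names(flip), colnames(dosage))) {
      stop_("orientation flags do not match dosage columns")
    }
    flip <- flip[colnames(dosage)]
  } else if (length(flip) != ncol(dosage)) {
    stop_("orientation flags do not match dosage columns")
  }
  if (any(flip)) {
    dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]
  }
  dosage
}

# Smallest penalty at which all coefficients are zero, in glmnet's
# parameterisation (columns standardised with 1/n variance, loss scaled
# by 1/n): lambda_max = max_j |<x_j_std, y - ybar>| / n for both the
# squared-error and (null-fit) logistic losses.
lambda_max <- function(x, y) {
  n <- nrow(x)
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  xs <- sweep(sweep(x, 2L, colMeans(x)), 2L, ifelse(sds > 0, sds, 1), `/`)
  xs[, sds == 0] <- 0
  max(abs(crossprod(xs, y - mean(y)))) / n
}

#' L1-penalised regression weights at a fixed penalty
#'
#' Fits the LASSO (squared-error loss for `"gaussian"`, logistic deviance
#' for `"binomial"`; intercept unpenalised, columns standardised
#' internally) by cyclic coordinate descent and returns coefficients on
#' the original dosage scale. At `lambda = 0` the fit coincides with the
#' unpenalised solution; at `lambda >= lambda_max` all weights are zero.
#'
#' @param x Predictor matrix (reoriented dosages), n x p with n >= 2.
#' @param y Outcome vector.
#' @param lambda Penalty, `>= 0`, in the `1/n`-scaled parameterisation
#'   (the glmnet convention).
#' @param family `"gaussian"` or `"binomial"`.
#' @return List with `intercept`, `weights` (named, length p) and
#'   `lambda`.
#' @export
lasso_fit <- function(x, y, lambda, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_("non-finite values in predictors or outcome")
  }
  if (nrow(x) < 2L) stop_("at least two observations required")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_("lambda must be a single non-negative number")
  }
  lmax <- lambda_max(x, y)
  if (lambda >= lmax || lmax == 0) {
    # closed form: all penalised coefficients zero, intercept = null fit
    b0 <- if (family == "gaussian") mean(y) else qlogis(mean(y))
    return(list(intercept = b0,
                weights = setNames(numeric(ncol(x)), colnames(x)),
                lambda = lambda))
  }
  # descending path into the target penalty stabilises the warm starts
  path <- sort(unique(c(exp(seq(log(lmax), log(max(lambda, lmax * 1e-4)),
                                length.out = 30L)), lambda)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = family, lambda = path,
                        standardize = TRUE, thresh = 1e-12)
  j <- which(abs(fit$lambda - lambda) < 1e-12 * max(1, lambda))
  b <- if (length(j)) {
    as.matrix(coef(fit))[, j[1L], drop = TRUE]
  } else {
    drop(as.matrix(coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                        family = family)))
  }
  list(intercept = as.numeric(b[1L]),
       weights = setNames(as.numeric(b[-1L]), colnames(x)),
       lambda = lambda)
}

#' Choose the LASSO penalty by inner cross-validation
#'
#' Minimises cross-validated prediction deviance over a logarithmic grid
#' from `lambda_max` down to `lambda_max / 1000`, then applies the
#' one-standard-error rule: the largest penalty whose CV loss is within
#' one standard error of the minimum (a parsimony tie-break that favours
#' sparse, transferable scores). Folds are stratified by outcome class
#' for binary traits and derived deterministically from `seed`.
#'
#' @param x Predictor matrix.
#' @param y Outcome vector.
#' @param family `"gaussian"` or `"binomial"`.
#' @param nfolds Inner fold count, `>= 2` (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return The selected penalty (scalar).
#' @export
choose_penalty <- function(x, y, family = c("gaussian", "binomial"),
                           nfolds = 5L, seed = 1L) {
  family <- match.arg(family)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nfolds < 2L) stop_("nfolds must be >= 2")
  n <- nrow(x)
  foldid <- with_seed_(seed, {
    if (family == "binomial") {
      f <- integer(n)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
      }
      f
    } else {
      sample(rep_len(seq_len(nfolds), n))
    }
  })
  cv <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                          nlambda = 100L, lambda.min.ratio = 0.001,
                          standardize = TRUE)
  if (length(cv$lambda) < 2L) stop_("degenerate penalty grid")
  cv$lambda.1se
}

#' Construct a genetic risk score model
#'
#' @param snp_ids Ordered SNP ids entering the score.
#' @param orientation Named logical: was the coded allele flipped toward
#'   the risk direction.
#' @param weights Named numeric LASSO coefficients (zeros allowed).
#' @param trait_kind `"fracture"` or `"bmd"`.
#' @param penalty The penalty value `lambda >= 0` used in the fit.
#' @return An object of class `GrsModel`.
#' @export
grs_model <- function(snp_ids, orientation, weights,
                      trait_kind = c("fracture", "bmd"), penalty) {
  trait_kind <- match.arg(trait_kind)
  snp_ids <- as.character(snp_ids)
  if (length(weights) != length(snp_ids)) {
    stop_("weights length must equal snp_ids length")
  }
  if (length(orientation) != length(snp_ids)) {
    stop_("orientation length must equal snp_ids length")
  }
  if (!is.numeric(penalty) || penalty < 0) stop_("penalty must be >= 0")
  structure(
    list(snp_ids = snp_ids,
         orientation = setNames(as.logical(orientation), snp_ids),
         weights = setNames(as.numeric(weights), snp_ids),
         trait_kind = trait_kind, penalty = penalty),
    class = "GrsModel"
  )
}

#' @export
print.GrsModel <- function(x, ...) {
  cat("GrsModel (", x$trait_kind, "): ", length(x$snp_ids), " SNPs, ",
      sum(x$weights != 0), " nonzero weights, lambda = ",
      signif(x$penalty, 4), "\n", sep = "")
  invisible(x)
}

#' Compute per-subject genetic risk scores
#'
#' `score_i = sum_j weight_j * dosage_ij` over risk-oriented dosages.
#' The dosage columns must carry exactly the model's SNPs (any order if
#' named); a mismatch is an error.
#'
#' @param dosage Reoriented subjects x SNPs matrix (see
#'   [apply_orientation()]; use [score_subjects()] to go straight from
#'   raw genotypes).
#' @param model A [grs_model()].
#' @return Numeric score per subject.
#' @export
#' @examples
#' m <- grs_model(c("a", "b", "c"), rep(FALSE, 3), c(0.2, -0.1, 0.3),
#'                "bmd", penalty = 0.1)
#' compute_grs(matrix(c(0, 1, 2), 1, dimnames = list("s1", c("a", "b", "c"))), m)
compute_grs <- function(dosage, model) {
  stopifnot(inherits(model, "GrsModel"))
  if (!is.matrix(dosage)) stop_("dosage must be a matrix")
  if (!is.null(colnames(dosage))) {
    if (!setequal(colnames(dosage), model$snp_ids)) {
      stop_("SNP mismatch between model and dosage matrix")
    }
    dosage <- dosage[, model$snp_ids, drop = FALSE]
  } else if (ncol(dosage) != length(model$snp_ids)) {
    stop_("SNP mismatch between model and dosage matrix")
  }
  drop(dosage %*% model$weights)
}

#' Score raw genotypes with a GRS model (orientation + weights)
#'
#' @param genotypes A [genotype_matrix()] containing the model's SNPs.
#' @param model A [grs_model()].
#' @return Named numeric score per subject.
#' @export
score_subjects <- function(genotypes, model) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"))
  missing <- setdiff(model$snp_ids, genotypes$snp_ids)
  if (length(missing)) {
    stop_("SNP mismatch: genotypes lack ", paste(missing, collapse = ", "))
  }
  d <- genotypes$dosage[, model$snp_ids, drop = FALSE]
  setNames(compute_grs(apply_orientation(d, model$orientation), model),
           genotypes$subject_ids)
}

#' Train a GRS on one training set
#'
#' The full per-fold recipe: orient risk alleles on the training rows,
#' select the penalty by inner cross-validation (unless given), and fit
#' the LASSO weights. Everything depends on the training rows only.
#'
#' @param dosage Training subjects x SNPs raw dosage matrix.
#' @param outcome Training outcome (binary for `"fracture"`).
#' @param trait_kind `"fracture"` or `"bmd"`.
#' @param seed Seed for the inner-CV fold assignment.
#' @param penalty Optional fixed penalty; if `NULL`, chosen by
#'   [choose_penalty()].
#' @param inner_folds Inner-CV fold count.
#' @return A [grs_model()].
#' @export
train_grs <- function(dosage, outcome, trait_kind = c("fracture", "bmd"),
                      seed = 1L, penalty = NULL, inner_folds = 5L) {
  trait_kind <- match.arg(trait_kind)
  family <- if (trait_kind == "fracture") "binomial" else "gaussian"
  ori <- orient_risk_alleles(dosage, outcome, trait_kind)
  lam <- penalty %||% choose_penalty(ori$dosage, outcome, family,
                                     nfolds = inner_folds, seed = seed)
  fit <- lasso_fit(ori$dosage, outcome, lam, family)
  grs_model(colnames(dosage), ori$flip, fit$weights, trait_kind, lam)
}

#' Serialize / restore a GRS model as a tab-delimited file
#'
#' Header comment lines record `trait_kind` and `lambda`; the body has
#' columns `snp_id`, `flipped`, `weight`.
#'
#' @param model A [grs_model()].
#' @param path File path.
#' @return `path` (write) or the restored `GrsModel` (read).
#' @export
write_grs_model <- function(model, path) {
  stopifnot(inherits(model, "GrsModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# trait_kind=", model$trait_kind),
               paste0("# lambda=", format(model$penalty, digits = 17)),
               "snp_id\tflipped\tweight"), con)
  writeLines(sprintf("%s\t%d\t%s", model$snp_ids,
                     as.integer(model$orientation),
                     format(model$weights, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname write_grs_model
#' @export
read_grs_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- function(key) sub(paste0("^# ", key, "="), "",
                          grep(paste0("^# ", key, "="), hdr, value = TRUE))
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  grs_model(tab$snp_id, tab$flipped == 1L, tab$weight,
            trait_kind = kv("trait_kind"), penalty = as.numeric(kv("lambda")))
}
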