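CRF_TERMS <- c("gender", "age", "height", "weight")

#' Model specifications of the six fracture/BMD risk models
#'
#' Model family and predictor set by id:
#' * `I-I`   logistic: fracture ~ CRFs
#' * `I-II`  logistic: fracture ~ CRFs + GRS (fracture-gene score)
#' * `I-III` logistic: fracture ~ CRFs + GRS (BMD-gene score)
#' * `II-I`  linear:   BMD ~ CRFs
#' * `II-II` linear:   BMD ~ GRS only
#' * `II-III` linear:  BMD ~ CRFs + GRS
#'
#' @param model_id One of the ids above.
#' @return List with `model_id`, `family` (`"binomial"`/`"gaussian"`),
#'   `outcome` (default outcome column), `terms`.
#' @export
model_spec <- function(model_id) {
  specs <- list(
    "I-I"    = list(family = "binomial", outcome = "fracture",
                    terms = CRF_TERMS),
    "I-II"   = list(family = "binomial", outcome = "fracture",
                    terms = c(CRF_TERMS, "GRS")),
    "I-III"  = list(family = "binomial", outcome = "fracture",
                    terms = c(CRF_TERMS, "GRS")),
    "II-I"   = list(family = "gaussian", outcome = "fn_bmd",
                    terms = CRF_TERMS),
    "II-II"  = list(family = "gaussian", outcome = "fn_bmd",
                    terms = "GRS"),
    "II-III" = list(family = "gaussian", outcome = "fn_bmd",
                    terms = c(CRF_TERMS, "GRS"))
  )
  if (!model_id %in% names(specs)) {
    stop_("unknown model id '", model_id, "' (expected one of ",
          paste(names(specs), collapse = ", "), ")")
  }
  c(list(model_id = model_id), specs[[model_id]])
}

#' Fit one risk model
#'
#' Maximum-likelihood logistic regression (IRLS via `stats::glm`) for the
#' fracture models, least squares for the BMD models, with
#' observed-information coefficient covariance. The GRS covariate must be
#' supplied exactly for the specs that include it. Perfect separation and
#' singular designs are rejected with a diagnostic.
#'
#' @param data Phenotype data.frame containing the outcome and CRF
#'   columns.
#' @param model_id Model id (see [model_spec()]).
#' @param grs Optional numeric GRS per row of `data`.
#' @param outcome Optional outcome column override (e.g. `"ls_bmd"`).
#' @return An object of class `RiskModel`: coefficients, covariance,
#'   terms, family, and the underlying fit.
#' @export
fit_model <- function(data, model_id, grs = NULL, outcome = NULL) {
  spec <- model_spec(model_id)
  needs_grs <- "GRS" %in% spec$terms
  if (needs_grs && is.null(grs)) {
    stop_("model ", model_id, " requires a GRS covariate")
  }
  if (!needs_grs && !is.null(grs)) {
    stop_("model ", model_id, " does not take a GRS covariate")
  }
  outcome <- outcome %||% spec$outcome
  if (!outcome %in% names(data)) {
    stop_("outcome column '", outcome, "' not found in data")
  }
  df <- data[, intersect(spec$terms, names(data)), drop = FALSE]
  if (needs_grs) {
    if (length(grs) != nrow(data)) stop_("GRS length mismatch")
    df$GRS <- as.numeric(grs)
  }
  miss <- setdiff(spec$terms, names(df))
  if (length(miss)) {
    stop_("data lacks predictor column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, spec$terms, drop = FALSE]
  df$.y <- data[[outcome]]
  fml <- as.formula(paste(".y ~", paste(spec$terms, collapse = " + ")))
  fit <- if (spec$family == "binomial") {
    withCallingHandlers(
      glm(fml, data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          stop_("possible perfect separation in model ", model_id,
                ": fitted probabilities of 0 or 1 occurred")
        }
        invokeRestart("muffleWarning")
      }
    )
  } else {
    lm(fml, data = df)
  }
  if (spec$family == "binomial") {
    mu <- fitted(fit)
    if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
      stop_("possible perfect separation in model ", model_id,
            ": fitted probabilities numerically 0 or 1 occurred")
    }
  }
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_("singular design in model ", model_id, ": aliased term(s) ",
          paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  structure(
    list(model_id = model_id, family = spec$family, terms = spec$terms,
         outcome = outcome, coefficients = cf, covariance = vcov(fit),
         fit = fit),
    class = "RiskModel"
  )
}

#' @export
print.RiskModel <- function(x, ...) {
  cat("RiskModel ", x$model_id, " (", x$family, "): ",
      paste(x$terms, collapse = " + "), "\n", sep = "")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Predict from a fitted risk model
#'
#' @param object A `RiskModel`.
#' @param newdata Data.frame with the model's predictor columns (plus
#'   `GRS` via the `grs` argument).
#' @param grs Optional GRS vector for specs that include it.
#' @param ... Unused.
#' @return Predicted probability (logistic) or outcome value (linear).
#' @export
predict.RiskModel <- function(object, newdata, grs = NULL, ...) {
  if ("GRS" %in% object$terms) {
    if (is.null(grs)) stop_("model ", object$model_id, " needs a GRS")
    newdata$GRS <- as.numeric(grs)
  }
  predict(object$fit, newdata = newdata, type = "response")
}

#' Odds ratios with 95% confidence intervals
#'
#' `OR = exp(beta)`, `CI = exp(beta +/- 1.96 SE)` for every non-intercept
#' term of a logistic risk model.
#'
#' @param model A logistic `RiskModel`.
#' @return Data.frame: `term`, `estimate`, `se`, `or`, `lower`, `upper`.
#' @export
odds_ratios <- function(model) {
  stopifnot(inherits(model, "RiskModel"))
  if (model$family != "binomial") {
    stop_("odds ratios are defined for logistic models only")
  }
  beta <- model$coefficients[-1L]
  se <- sqrt(diag(model$covariance))[-1L]
  data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    or = unname(exp(beta)),
    lower = unname(exp(beta - 1.96 * se)),
    upper = unname(exp(beta + 1.96 * se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Fold assignment over canonicalised subject ids: stratified by outcome
# class for binary outcomes (keeps every fold two-class), simple random
# otherwise. Sizes differ by at most one.
make_folds <- function(subject_ids, outcome, nfolds, seed,
                       stratify = FALSE) {
  ord <- order(subject_ids)
  ids <- subject_ids[ord]
  y <- outcome[ord]
  fold <- integer(length(ids))
  with_seed_(seed, {
    if (stratify) {
      for (cls in sort(unique(y))) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
      }
    } else {
      fold[] <- sample(rep_len(seq_len(nfolds), length(ids)))
    }
  })
  setNames(fold, ids)[subject_ids]
}

#' K-fold cross-validated risk-model evaluation
#'
#' Partitions the cohort into `nfolds` equal-size folds (stratified by
#' case status for binary outcomes), and for every requested model spec
#' runs the full training recipe on the 9-of-10 training folds only:
#' risk-allele orientation, inner-CV penalty choice, LASSO weights, and
#' the regression fit. Held-out subjects are scored by the model not
#' trained on them; out-of-fold predictions are pooled. The identical
#' fold assignment is reused across specs so model comparisons are
#' paired.
#'
#' @param cohort A `Cohort` (or list with `genotypes` and `phenotypes`).
#' @param specs Character vector of model ids (see [model_spec()]).
#' @param seed Top-level seed: fold assignment and per-fold inner-CV
#'   seeds are derived from it.
#' @param nfolds Fold count (default 10).
#' @param grs_snps Optional named list, model id -> SNP id vector used
#'   for that spec's GRS (defaults to all SNPs). This is how a
#'   fracture-gene score and a BMD-gene score are distinguished inside
#'   one sample.
#' @param outcome Optional outcome column override for all specs.
#' @param penalty Optional fixed LASSO penalty (skips the inner CV).
#' @return Named list of `CvRun` objects, one per spec: fold assignment,
#'   per-fold `GrsModel`/`RiskModel`, pooled out-of-fold predictions,
#'   per-fold test MSE (linear family), and the outcome vector.
#' @export
cross_validate <- function(cohort, specs, seed = 1L, nfolds = 10L,
                           grs_snps = NULL, outcome = NULL,
                           penalty = NULL) {
  geno <- cohort$genotypes
  pheno <- cohort$phenotypes
  if (nrow(pheno) < 20L) stop_("need at least 20 subjects for CV")
  spec0 <- model_spec(specs[[1L]])
  outcome_col <- outcome %||% spec0$outcome
  for (s in specs) {
    sp <- model_spec(s)
    if (sp$family != spec0$family) {
      stop_("all specs in one run must share a model family")
    }
  }
  y <- pheno[[outcome_col]]
  if (is.null(y)) stop_("outcome column '", outcome_col, "' not found")
  binary <- spec0$family == "binomial"
  fold <- make_folds(pheno$subject_id, y, nfolds,
                     derive_seed(seed, "folds"), stratify = binary)
  if (binary) {
    for (k in seq_len(nfolds)) {
      if (length(unique(y[fold == k])) < 2L) {
        stop_("fold ", k, " has a single outcome class; use stratified ",
              "folds or fewer folds")
      }
    }
  }
  trait_kind <- if (binary) "fracture" else "bmd"
  out <- lapply(specs, function(spec_id) {
    sp <- model_spec(spec_id)
    needs_grs <- "GRS" %in% sp$terms
    snp_set <- (grs_snps[[spec_id]] %||% geno$snp_ids)
    oof <- setNames(rep(NA_real_, nrow(pheno)), pheno$subject_id)
    fold_grs <- vector("list", nfolds)
    fold_models <- vector("list", nfolds)
    fold_mse <- rep(NA_real_, nfolds)
    for (k in seq_len(nfolds)) {
      tr <- fold != k
      te <- !tr
      grs_tr <- grs_te <- NULL
      if (needs_grs) {
        d_tr <- geno$dosage[tr, snp_set, drop = FALSE]
        gm <- train_grs(d_tr, y[tr], trait_kind,
                        seed = derive_seed(seed, paste0(spec_id, "-inner-", k)),
                        penalty = penalty)
        fold_grs[[k]] <- gm
        grs_tr <- compute_grs(apply_orientation(d_tr, gm$orientation), gm)
        d_te <- geno$dosage[te, snp_set, drop = FALSE]
        grs_te <- compute_grs(apply_orientation(d_te, gm$orientation), gm)
      }
      pheno_tr <- pheno[tr, , drop = FALSE]
      pheno_te <- pheno[te, , drop = FALSE]
      if (needs_grs && var(grs_tr) == 0) {
        # LASSO kept no SNP: the score is uninformative, fall back to the
        # same spec without the GRS term (GRS coefficient recorded as 0)
        rm_fit <- fit_drop_grs(pheno_tr, spec_id, outcome_col)
        fold_models[[k]] <- rm_fit
        pred <- predict(rm_fit$fit, newdata = pheno_te, type = "response")
      } else {
        rm_fit <- fit_model(pheno_tr, spec_id, grs = grs_tr,
                            outcome = outcome_col)
        fold_models[[k]] <- rm_fit
        pred <- predict(rm_fit, pheno_te, grs = grs_te)
      }
      oof[te] <- pred
      if (!binary) fold_mse[k] <- mean((y[te] - pred)^2)
    }
    structure(
      list(model_id = spec_id, fold_assignment = fold, oof_prediction = oof,
           fold_grs = fold_grs, fold_models = fold_models,
           fold_mse = if (binary) NULL else fold_mse,
           outcome = setNames(y, pheno$subject_id),
           outcome_col = outcome_col, family = sp$family,
           nfolds = nfolds, seed = seed),
      class = "CvRun"
    )
  })
  names(out) <- specs
  out
}

# Same spec with the GRS term removed (degenerate all-zero-weight folds).
fit_drop_grs <- function(data, model_id, outcome_col) {
  sp <- model_spec(model_id)
  terms <- setdiff(sp$terms, "GRS")
  df <- data
  df$.y <- data[[outcome_col]]
  fml <- if (length(terms)) {
    as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  } else {
    .y ~ 1
  }
  fit <- if (sp$family == "binomial") {
    glm(fml, data = df, family = binomial())
  } else {
    lm(fml, data = df)
  }
  cf <- c(coef(fit), GRS = 0)
  v0 <- vcov(fit)
  v <- rbind(cbind(v0, GRS = 0), GRS = 0) # zero-variance row for the
  # dropped GRS keeps the coefficient table shape
  structure(
    list(model_id = model_id, family = sp$family, terms = sp$terms,
         outcome = outcome_col, coefficients = cf,
         covariance = v, fit = fit, grs_dropped = TRUE),
    class = "RiskModel"
  )
}

#' @export
print.CvRun <- function(x, ...) {
  cat("CvRun ", x$model_id, ": ", x$nfolds, " folds, n = ",
      length(x$oof_prediction), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}
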