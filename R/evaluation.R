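#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen event receives a higher prediction
#' than a randomly chosen non-event, with ties counted one half —
#' computed from midranks, equivalent to exhaustive pair counting.
#'
#' @param predictions Numeric risk predictions.
#' @param outcomes 0/1 outcome vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.8, 0.5, 0.5, 0.2), c(1, 1, 0, 0)) # 0.875
auc <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes)) stop_("length mismatch")
  if (!all(outcomes %in% c(0, 1))) stop_("outcomes must be coded 0/1")
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) {
    stop_("both outcome classes must be present to compute an AUC")
  }
  r <- rank(predictions, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assign predicted probabilities to clinical risk groups
#'
#' Three categories with half-open boundaries: lower risk `p < 0.10`,
#' middle risk `0.10 <= p < 0.15`, higher risk `p >= 0.15` (the upper
#' boundary belongs to the higher group).
#'
#' @param probability Numeric vector of probabilities in `[0, 1]`.
#' @param cutoffs Length-2 increasing cutoff vector, default
#'   `c(0.10, 0.15)`.
#' @return Ordered factor with levels `lower < middle < higher`.
#' @export
#' @examples
#' assign_risk_group(c(0.0999, 0.10, 0.15))
assign_risk_group <- function(probability, cutoffs = c(0.10, 0.15)) {
  if (length(cutoffs) != 2L || cutoffs[1] >= cutoffs[2] ||
      cutoffs[1] <= 0 || cutoffs[2] >= 1) {
    stop_("cutoffs must be strictly increasing within (0, 1)")
  }
  if (anyNA(probability) || any(probability < 0 | probability > 1)) {
    stop_("probabilities must lie in [0, 1]")
  }
  cut(probability, breaks = c(-Inf, cutoffs, Inf),
      labels = c("lower", "middle", "higher"),
      right = FALSE, ordered_result = TRUE)
}

#' Reclassification cross-tabulation of two risk models
#'
#' Cross-tabulates subjects' risk categories under a baseline and an
#' augmented model, separately for events (outcome 1) and non-events
#' (outcome 0). "Up" movement means the augmented category is strictly
#' above the baseline one; "down" strictly below.
#'
#' @param p_base,p_augmented Aligned per-subject predicted probabilities.
#' @param outcomes Aligned 0/1 outcome vector.
#' @param cutoffs Risk-group cutoffs, see [assign_risk_group()].
#' @return An object of class `ReclassificationResult`: `cutoffs`,
#'   `table_event` and `table_nonevent` (3x3 count matrices, rows =
#'   baseline category, columns = augmented category), `n_event`,
#'   `n_nonevent`.
#' @export
reclassification_table <- function(p_base, p_augmented, outcomes,
                                   cutoffs = c(0.10, 0.15)) {
  if (length(p_base) != length(p_augmented) ||
      length(p_base) != length(outcomes)) {
    stop_("p_base, p_augmented and outcomes must have equal length")
  }
  g_base <- assign_risk_group(p_base, cutoffs)
  g_aug <- assign_risk_group(p_augmented, cutoffs)
  tab <- function(keep) {
    t <- table(baseline = g_base[keep], augmented = g_aug[keep])
    matrix(as.integer(t), 3L, 3L, dimnames = dimnames(t))
  }
  structure(
    list(cutoffs = cutoffs,
         table_event = tab(outcomes == 1),
         table_nonevent = tab(outcomes == 0),
         n_event = sum(outcomes == 1),
         n_nonevent = sum(outcomes == 0)),
    class = "ReclassificationResult"
  )
}

#' Build a ReclassificationResult from printed 3x3 count tables
#'
#' For checking published reclassification tables directly: supply the
#' event and non-event cross-tabulations (rows = baseline category
#' lower/middle/higher, columns = augmented category).
#'
#' @param table_event,table_nonevent 3x3 non-negative integer matrices.
#' @param cutoffs Risk-group cutoffs the tables were built with.
#' @return A `ReclassificationResult`.
#' @export
reclassification_from_counts <- function(table_event, table_nonevent,
                                         cutoffs = c(0.10, 0.15)) {
  chk <- function(m, what) {
    if (!is.matrix(m) || !all(dim(m) == 3L)) {
      stop_(what, " must be a 3x3 matrix")
    }
    if (anyNA(m) || any(m < 0) || any(m != floor(m))) {
      stop_(what, " must contain non-negative integer counts")
    }
    if (sum(m) == 0) stop_(what, " is empty (all counts zero)")
    storage.mode(m) <- "integer"
    m
  }
  structure(
    list(cutoffs = cutoffs,
         table_event = chk(table_event, "table_event"),
         table_nonevent = chk(table_nonevent, "table_nonevent"),
         n_event = sum(table_event), n_nonevent = sum(table_nonevent)),
    class = "ReclassificationResult"
  )
}

#' @export
print.ReclassificationResult <- function(x, ...) {
  cat("ReclassificationResult:", x$n_event, "events,", x$n_nonevent,
      "non-events\nEvents:\n")
  print(x$table_event)
  cat("Non-events:\n")
  print(x$table_nonevent)
  invisible(x)
}

upper_count <- function(m) sum(m[upper.tri(m)])
lower_count <- function(m) sum(m[lower.tri(m)])

#' Net reclassification improvement
#'
#' `NRI = Pr(up | event) - Pr(down | event) + Pr(down | non-event) -
#' Pr(up | non-event)`, where up/down are strict category movements from
#' the baseline to the augmented model.
#'
#' @param result A `ReclassificationResult`.
#' @return An object of class `NriResult`: the four movement
#'   proportions, the movement counts, group sizes, and `nri`.
#' @export
compute_nri <- function(result) {
  stopifnot(inherits(result, "ReclassificationResult"))
  if (result$n_event <= 0 || result$n_nonevent <= 0) {
    stop_("both outcome groups must be non-empty")
  }
  up_e <- as.integer(upper_count(result$table_event))
  down_e <- as.integer(lower_count(result$table_event))
  up_ne <- as.integer(upper_count(result$table_nonevent))
  down_ne <- as.integer(lower_count(result$table_nonevent))
  p_up_event <- up_e / result$n_event
  p_down_event <- down_e / result$n_event
  p_up_nonevent <- up_ne / result$n_nonevent
  p_down_nonevent <- down_ne / result$n_nonevent
  structure(
    list(p_up_event = p_up_event, p_down_event = p_down_event,
         p_up_nonevent = p_up_nonevent, p_down_nonevent = p_down_nonevent,
         up_event = up_e, down_event = down_e,
         up_nonevent = up_ne, down_nonevent = down_ne,
         n_event = as.integer(result$n_event),
         n_nonevent = as.integer(result$n_nonevent),
         nri = (p_up_event - p_down_event) +
           (p_down_nonevent - p_up_nonevent)),
    class = "NriResult"
  )
}

#' Asymptotic Z-test for NRI = 0
#'
#' `z = NRI / sqrt((p_up_e + p_down_e) / n_e + (p_up_ne + p_down_ne) /
#' n_ne)` with a two-sided normal p-value. No movement at all gives
#' `z = 0, p = 1` by convention.
#'
#' @param nri_result An `NriResult` from [compute_nri()].
#' @return The `NriResult` augmented with `z` and `p_value`.
#' @export
nri_ztest <- function(nri_result) {
  stopifnot(inherits(nri_result, "NriResult"))
  v <- (nri_result$p_up_event + nri_result$p_down_event) /
    nri_result$n_event +
    (nri_result$p_up_nonevent + nri_result$p_down_nonevent) /
    nri_result$n_nonevent
  if (v == 0) {
    if (nri_result$nri != 0) {
      stop_("zero movement variance with nonzero NRI (inconsistent counts)")
    }
    nri_result$z <- 0
    nri_result$p_value <- 1
    return(nri_result)
  }
  nri_result$z <- nri_result$nri / sqrt(v)
  nri_result$p_value <- 2 * pnorm(-abs(nri_result$z))
  nri_result
}

#' @export
print.NriResult <- function(x, ...) {
  cat(sprintf(
    "NRI = %.4f%% (event: up %d / down %d of %d; non-event: up %d / down %d of %d)\n",
    100 * x$nri, x$up_event, x$down_event, x$n_event,
    x$up_nonevent, x$down_nonevent, x$n_nonevent))
  if (!is.null(x$z)) {
    cat(sprintf("Z = %.3f, two-sided p = %.3f\n", x$z, x$p_value))
  }
  invisible(x)
}

#' Combine report-style component percentages into a printed NRI
#'
#' Published reclassification tables report the four movement components
#' as two-decimal percentages; the table-level NRI is their signed sum,
#' `(up_e - down_e) + (down_ne - up_ne)`. Combining the rounded
#' components (as tables print them) can differ from the exact-fraction
#' NRI in the last decimal, so both styles are useful.
#'
#' @param up_event_pct,down_event_pct,down_nonevent_pct,up_nonevent_pct
#'   Component percentages as printed.
#' @return The combined NRI percentage.
#' @export
#' @examples
#' combine_printed_components(0, 1.14, 2.00, 0.30) # 0.56
combine_printed_components <- function(up_event_pct, down_event_pct,
                                       down_nonevent_pct, up_nonevent_pct) {
  (up_event_pct - down_event_pct) + (down_nonevent_pct - up_nonevent_pct)
}

#' Format a proportion as a report-style percentage
#'
#' Two decimals, round half away from zero (the convention of printed
#' reclassification tables). The exact fraction should always be kept
#' alongside.
#'
#' @param p Proportion in `[0, 1]`.
#' @return Numeric percentage rounded to two decimals.
#' @export
percent_printed <- function(p) round_half_away(100 * p, 2L)

#' Paired MSE comparison of two cross-validated linear models
#'
#' Per-fold test-set mean squared errors of two `CvRun`s with identical
#' fold assignments, compared by a two-sided paired t-test on the
#' fold-level differences. All-zero differences give `t = 0, p = 1`.
#'
#' @param cv_a,cv_b Linear-family `CvRun` objects from one
#'   [cross_validate()] call (identical folds required).
#' @return An object of class `MseComparison`: per-fold MSE vectors,
#'   `mean_diff` (a minus b), `t`, `df`, `p_value`.
#' @export
mse_compare <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "CvRun"), inherits(cv_b, "CvRun"))
  if (is.null(cv_a$fold_mse) || is.null(cv_b$fold_mse)) {
    stop_("MSE comparison is defined for linear-family CV runs")
  }
  if (!identical(cv_a$fold_assignment, cv_b$fold_assignment)) {
    stop_("fold assignments differ; compare runs from one cross_validate call")
  }
  d <- cv_a$fold_mse - cv_b$fold_mse
  k <- length(d)
  if (sd(d) == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    t_stat <- mean(d) / (sd(d) / sqrt(k))
    p <- 2 * pt(-abs(t_stat), df = k - 1)
  }
  structure(
    list(model_a = cv_a$model_id, model_b = cv_b$model_id,
         mse_a = cv_a$fold_mse, mse_b = cv_b$fold_mse,
         mean_diff = mean(d), t = t_stat, df = k - 1, p_value = p),
    class = "MseComparison"
  )
}

#' @export
print.MseComparison <- function(x, ...) {
  cat(sprintf(
    "MSE %s vs %s: mean(MSE_a) = %.5g, mean(MSE_b) = %.5g, diff = %.3g, t = %.3f, p = %.4f\n",
    x$model_a, x$model_b, mean(x$mse_a), mean(x$mse_b), x$mean_diff,
    x$t, x$p_value))
  invisible(x)
}

# Explained variation of a term subset: R^2 for linear models, McFadden
# pseudo-R^2 (1 - deviance ratio) for logistic ones. Empty subset -> 0.
subset_r2 <- function(y, df, terms, family) {
  fml <- if (length(terms)) {
    as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  } else {
    .y ~ 1
  }
  df$.y <- y
  if (family == "binomial") {
    fit <- glm(fml, data = df, family = binomial())
    1 - fit$deviance / fit$null.deviance
  } else {
    fit <- lm(fml, data = df)
    1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
}

#' Relative importance of predictor groups
#'
#' Decomposes a model's explained variation (R-squared for linear
#' models, McFadden pseudo-R-squared for logistic ones) into
#' per-predictor shares by averaging each predictor's sequential
#' contribution over all orderings of the predictors (the Shapley/LMG
#' decomposition). Because adding a predictor never decreases explained
#' variation, every share is non-negative, and by construction the
#' shares sum exactly to the full model's explained variation.
#'
#' @param model A fitted `RiskModel`.
#' @param data The data the model was fitted on (with CRF columns).
#' @param grs GRS vector if the model includes one.
#' @return Named numeric of per-term shares (same units as R-squared),
#'   with attribute `total` = full-model explained variation. Multiply
#'   by 100 for the percent scale.
#' @export
relative_importance <- function(model, data, grs = NULL) {
  stopifnot(inherits(model, "RiskModel"))
  terms <- model$terms
  df <- data[, intersect(terms, names(data)), drop = FALSE]
  if ("GRS" %in% terms) {
    if (is.null(grs)) stop_("model includes a GRS; supply `grs`")
    df$GRS <- as.numeric(grs)
  }
  y <- data[[model$outcome]]
  p <- length(terms)
  # Shapley value over subsets: weight |S|! (p-|S|-1)! / p!
  n_sub <- 2^p
  r2 <- numeric(n_sub)
  for (mask in seq_len(n_sub) - 1L) {
    sub <- terms[bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L]
    r2[mask + 1L] <- subset_r2(y, df, sub, model$family)
  }
  lw <- lfactorial(0:p) # log factorials, reused
  shares <- setNames(numeric(p), terms)
  for (g in seq_len(p)) {
    bit <- 2^(g - 1L)
    for (mask in seq_len(n_sub) - 1L) {
      if (bitwAnd(mask, bit) > 0L) next
      s <- sum(bitwAnd(mask, 2^(seq_len(p) - 1L)) > 0L)
      w <- exp(lw[s + 1L] + lw[p - s] - lw[p + 1L])
      shares[g] <- shares[g] + w * (r2[mask + bit + 1L] - r2[mask + 1L])
    }
  }
  structure(shares, total = r2[n_sub])
}
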