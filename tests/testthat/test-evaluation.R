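test_that("AUC handles separation, ties and label inversion", {
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(0, 0, 1, 1)), 0.0)
  # tie between one case and one control counts one half: 3.5 / 4
  expect_equal(auc(c(0.8, 0.5, 0.5, 0.2), c(1, 1, 0, 0)), 0.875)
  expect_error(auc(c(0.2, 0.3), c(1, 1)), "both outcome classes")
})

test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    p <- round(runif(n), sample(1:3, 1)) # coarse rounding induces ties
    expect_equal(auc(p, y), auc_paircount(p, y), tolerance = 1e-12)
  }
})

test_that("risk groups use half-open boundaries", {
  g <- assign_risk_group(c(0.0999, 0.10, 0.1499, 0.15, 1.0, 0))
  expect_identical(as.character(g),
                   c("lower", "middle", "middle", "higher", "higher",
                     "lower"))
  expect_true(is.ordered(g))
  expect_error(assign_risk_group(1.2), "\\[0, 1\\]")
  expect_error(assign_risk_group(0.5, cutoffs = c(0.2, 0.1)), "increasing")
})

test_that("reclassification table matches a brute-force double loop", {
  # identity: no movement at all
  p <- c(0.05, 0.12, 0.3, 0.14)
  y <- c(1, 0, 1, 0)
  r <- reclassification_table(p, p, y)
  expect_identical(sum(diag(r$table_event)), r$n_event)
  expect_identical(sum(diag(r$table_nonevent)), r$n_nonevent)

  # a single event moving lower -> higher counts as up
  r2 <- reclassification_table(0.09, 0.16, 1)
  expect_identical(r2$table_event["lower", "higher"], 1L)
  expect_identical(sum(r2$table_event) - 1L, 0L)

  set.seed(102)
  for (i in 1:20) {
    n <- 200
    pb <- runif(n, 0, 0.3)
    pa <- pmin(pmax(pb + rnorm(n, 0, 0.05), 0), 1)
    yy <- rbinom(n, 1, 0.4)
    ours <- reclassification_table(pb, pa, yy)
    oracle <- reclass_bruteforce(pb, pa, yy)
    expect_identical(unname(ours$table_event), oracle$event)
    expect_identical(unname(ours$table_nonevent), oracle$nonevent)
  }
  expect_error(reclassification_table(c(0.1, 0.2), 0.1, c(1, 0)),
               "equal length")
})

test_that("NRI reproduces the published fracture-GRS table arithmetic", {
  nri <- compute_nri(reclassification_from_counts(table5_event,
                                                  table5_nonevent))
  expect_identical(c(nri$up_event, nri$down_event), c(0L, 4L))
  expect_identical(c(nri$up_nonevent, nri$down_nonevent), c(1L, 7L))
  expect_equal(nri$nri, 2 / 350)
  expect_equal(percent_printed(nri$p_down_event), 1.14)
  expect_equal(percent_printed(nri$p_down_nonevent), 2.00)
  # identity: nri equals the four-proportion formula exactly
  expect_identical(nri$nri, (nri$p_up_event - nri$p_down_event) +
                     (nri$p_down_nonevent - nri$p_up_nonevent))
  z <- nri_ztest(nri)
  expect_equal(z$z, 0.5774, tolerance = 1e-3)
  expect_equal(z$p_value, 0.5637, tolerance = 1e-3)
  # published two-decimal P of 0.57 is matched to a percent
  expect_lt(abs(z$p_value - 0.57), 0.01)
})

test_that("NRI reproduces the published BMD-GRS table arithmetic", {
  nri <- nri_ztest(compute_nri(reclassification_from_counts(
    table6_event, table6_nonevent)))
  expect_identical(c(nri$up_event, nri$down_event), c(4L, 4L))
  expect_equal(nri$p_up_event - nri$p_down_event, 0) # event net exactly 0
  expect_equal(nri$nri, 4 / 350)
  expect_equal(nri$z, 1.069, tolerance = 1e-3)
  expect_equal(nri$p_value, 0.285, tolerance = 5e-3)
})

test_that("NRI Z-test degenerates gracefully and scales as sqrt(n)", {
  none <- matrix(c(5L, 0L, 0L, 0L, 5L, 0L, 0L, 0L, 5L), 3, 3)
  z0 <- nri_ztest(compute_nri(reclassification_from_counts(none, none)))
  expect_identical(c(z0$z, z0$p_value), c(0, 1))

  z1 <- nri_ztest(compute_nri(reclassification_from_counts(
    table6_event, table6_nonevent)))
  z2 <- nri_ztest(compute_nri(reclassification_from_counts(
    2L * table6_event, 2L * table6_nonevent)))
  expect_equal(z2$z, sqrt(2) * z1$z, tolerance = 1e-12)
})

test_that("printed-component combination reproduces published NRIs", {
  expect_equal(combine_printed_components(
    table5_printed$up_event, table5_printed$down_event,
    table5_printed$down_nonevent, table5_printed$up_nonevent), 0.56)
  expect_equal(combine_printed_components(
    table6_printed$up_event, table6_printed$down_event,
    table6_printed$down_nonevent, table6_printed$up_nonevent), 1.13)
})

test_that("paired MSE comparison is antisymmetric with exact degeneracy", {
  co <- small_bmd_cohort(seed = 111, n = 200)
  cv <- cross_validate(co, c("II-I", "II-III"), seed = 11)
  ab <- mse_compare(cv[["II-I"]], cv[["II-III"]])
  ba <- mse_compare(cv[["II-III"]], cv[["II-I"]])
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$mean_diff, -ba$mean_diff)

  self <- mse_compare(cv[["II-I"]], cv[["II-I"]])
  expect_identical(c(self$t, self$p_value), c(0, 1))

  cv2 <- cross_validate(co, "II-I", seed = 12)
  expect_error(mse_compare(cv[["II-I"]], cv2[["II-I"]]), "fold assignments")
})

test_that("an informative model beats a null model on MSE", {
  hits <- vapply(1:5, function(seed) {
    co <- small_bmd_cohort(seed = 300 + seed, n = 400,
                           crf_effects = c(gender = -0.05, age = -0.003,
                                           height = 0.001, weight = 0.004))
    cv <- cross_validate(co, c("II-I", "II-II"), seed = seed)
    # II-I (CRFs) should predict; II-II rests on a weak GRS
    cmp <- mse_compare(cv[["II-I"]], cv[["II-II"]])
    cmp$mean_diff < 0 && cmp$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("relative importance decomposes explained variation exactly", {
  co <- small_bmd_cohort(seed = 112, n = 300)
  fit <- fit_model(co$phenotypes, "II-I")
  ri <- relative_importance(fit, co$phenotypes)
  expect_named(ri, c("gender", "age", "height", "weight"))
  expect_true(all(ri >= -1e-12))
  r2_full <- summary(fit$fit)$r.squared
  expect_equal(sum(ri), r2_full, tolerance = 1e-10)
  expect_equal(attr(ri, "total"), r2_full, tolerance = 1e-10)

  # single predictor: its share is the whole explained variation
  fit1 <- fit_model(co$phenotypes, "II-II", grs = co$phenotypes$weight)
  ri1 <- relative_importance(fit1, co$phenotypes,
                             grs = co$phenotypes$weight)
  expect_equal(unname(ri1[["GRS"]]), attr(ri1, "total"))

  # two orthogonal predictors with exactly equal univariate R2 share
  # the explained variation equally (noise-free symmetric design)
  n <- 8
  a <- rep(c(-1, 1), n / 2)
  b <- rep(c(-1, -1, 1, 1), n / 4)
  y <- a + b
  df <- data.frame(subject_id = sprintf("s%d", 1:n), gender = 0,
                   age = 50, height = 160, weight = 60, fn_bmd = y,
                   A = a, B = b)
  fitm <- structure(list(model_id = "custom", family = "gaussian",
                         terms = c("A", "B"), outcome = "fn_bmd"),
                    class = "RiskModel")
  rim <- relative_importance(fitm, df)
  expect_equal(unname(rim[["A"]]), unname(rim[["B"]]), tolerance = 1e-12)
})

test_that("logistic relative importance uses McFadden pseudo-R2", {
  co <- small_fracture_cohort(seed = 113, n = 200)
  fit <- fit_model(co$phenotypes, "I-I")
  ri <- relative_importance(fit, co$phenotypes)
  g <- fit$fit
  mcfadden <- 1 - g$deviance / g$null.deviance
  expect_equal(sum(ri), mcfadden, tolerance = 1e-10)
  expect_true(all(ri >= -1e-12))
})
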