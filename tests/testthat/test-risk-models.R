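test_that("model specs carry the documented families and terms", {
  expect_identical(model_spec("I-I")$terms,
                   c("gender", "age", "height", "weight"))
  expect_identical(model_spec("I-I")$family, "binomial")
  expect_identical(model_spec("II-II")$terms, "GRS")
  expect_identical(model_spec("II-III")$family, "gaussian")
  expect_true("GRS" %in% model_spec("I-II")$terms)
  expect_error(model_spec("III-I"), "unknown model id")
})

test_that("linear fit interpolates a noise-free outcome exactly", {
  df <- data.frame(subject_id = sprintf("s%d", 1:30),
                   gender = rep(c(0, 1), 15), age = seq(30, 59),
                   height = rnorm(30, 165, 5), weight = rnorm(30, 60, 5))
  df$fn_bmd <- 1 + 2 * df$age
  fit <- fit_model(df, "II-I")
  expect_equal(unname(coef(fit$fit)[c("(Intercept)", "age")]), c(1, 2),
               tolerance = 1e-8)
  expect_equal(unname(coef(fit$fit)[c("gender", "height", "weight")]),
               c(0, 0, 0), tolerance = 1e-8)
})

test_that("logistic fit matches glm and keeps null effects near zero", {
  co <- small_fracture_cohort(seed = 91, n = 300, frac_causal = 0)
  ph <- co$phenotypes
  fit <- fit_model(ph, "I-I")
  ref <- glm(fracture ~ gender + age + height + weight, data = ph,
             family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-10)

  # a pure-noise GRS covariate stays within 3 SE of zero
  set.seed(92)
  grs <- rnorm(nrow(ph))
  fit2 <- fit_model(ph, "I-II", grs = grs)
  z <- fit2$coefficients[["GRS"]] /
    sqrt(diag(fit2$covariance)[["GRS"]])
  expect_lt(abs(z), 3)
})

test_that("GRS covariate contract is enforced", {
  co <- small_fracture_cohort(seed = 93, n = 60)
  ph <- co$phenotypes
  expect_error(fit_model(ph, "I-II"), "requires a GRS")
  expect_error(fit_model(ph, "I-I", grs = rnorm(60)), "does not take")
  expect_error(fit_model(ph, "I-II", grs = rnorm(10)), "length mismatch")
})

test_that("perfect separation and singular designs are diagnosed", {
  df <- data.frame(subject_id = sprintf("s%d", 1:40),
                   gender = rep(c(0, 1), 20),
                   age = c(rep(50, 20), rep(80, 20)),
                   height = rnorm(40, 160, 5), weight = rnorm(40, 60, 5),
                   fracture = c(rep(0, 20), rep(1, 20)))
  expect_error(fit_model(df, "I-I"), "separation")

  df2 <- df
  df2$fracture <- withr::with_seed(7, rbinom(40, 1, 0.5))
  df2$age <- withr::with_seed(8, rnorm(40, 65, 8))
  df2$weight <- df2$height # aliased column
  expect_error(fit_model(df2, "I-I"), "singular")
})

test_that("odds ratios exponentiate coefficients with 95% CIs", {
  co <- small_fracture_cohort(seed = 94, n = 200)
  fit <- fit_model(co$phenotypes, "I-I")
  ors <- odds_ratios(fit)
  expect_identical(ors$term, c("gender", "age", "height", "weight"))
  expect_equal(ors$or, exp(ors$estimate))
  expect_equal(ors$lower, exp(ors$estimate - 1.96 * ors$se))
  expect_true(all(ors$lower < ors$or & ors$or < ors$upper))
  expect_true(all(ors$lower > 0))
  # beta = ln 2, se = 0.1 -> OR 2.000, CI (1.644, 2.433)
  expect_equal(exp(log(2) + c(-1, 0, 1) * 1.96 * 0.1),
               c(1.644, 2.000, 2.433), tolerance = 5e-4)
  bmdco <- small_bmd_cohort(seed = 95, n = 60)
  expect_error(odds_ratios(fit_model(bmdco$phenotypes, "II-I")), "logistic")
})

test_that("cross-validation partitions into equal stratified folds", {
  co <- small_fracture_cohort(seed = 95, n = 700)
  cv <- cross_validate(co, "I-I", seed = 5)
  fold <- cv[["I-I"]]$fold_assignment
  expect_true(all(table(fold) == 70L))
  expect_identical(sort(unique(fold)), 1:10)
  # stratification: each fold holds 35 cases
  y <- setNames(co$phenotypes$fracture, co$phenotypes$subject_id)
  per_fold_cases <- tapply(y[names(fold)], fold, sum)
  expect_true(all(per_fold_cases == 35))
})

test_that("out-of-fold predictions are probabilities, one per subject", {
  co <- small_fracture_cohort(seed = 96, n = 100)
  cv <- cross_validate(co, c("I-I", "I-II"), seed = 6)
  for (run in cv) {
    expect_false(anyNA(run$oof_prediction))
    expect_true(all(run$oof_prediction >= 0 & run$oof_prediction <= 1))
    expect_identical(names(run$oof_prediction), co$phenotypes$subject_id)
  }
  # paired comparability across specs
  expect_identical(cv[["I-I"]]$fold_assignment,
                   cv[["I-II"]]$fold_assignment)
})

test_that("pooled metrics are invariant to subject order", {
  co <- small_fracture_cohort(seed = 97, n = 100)
  cv1 <- cross_validate(co, "I-I", seed = 7)
  perm <- withr::with_seed(1, sample(nrow(co$phenotypes)))
  co2 <- co
  co2$phenotypes <- co$phenotypes[perm, , drop = FALSE]
  co2$genotypes <- genotype_matrix(co$genotypes$dosage[perm, , drop = FALSE],
                                   snp_meta = co$genotypes$snp_meta)
  cv2 <- cross_validate(co2, "I-I", seed = 7)
  # canonicalised ids -> identical assignment and identical pooled AUC
  expect_identical(sort(names(cv1[["I-I"]]$fold_assignment)),
                   sort(names(cv2[["I-I"]]$fold_assignment)))
  expect_equal(cv1[["I-I"]]$fold_assignment[co$phenotypes$subject_id],
               cv2[["I-I"]]$fold_assignment[co$phenotypes$subject_id])
  a1 <- auc(cv1[["I-I"]]$oof_prediction, co$phenotypes$fracture)
  a2 <- auc(cv2[["I-I"]]$oof_prediction[co$phenotypes$subject_id],
            co$phenotypes$fracture)
  expect_equal(a1, a2)
})

test_that("cross-validation never leaks held-out rows into training", {
  co <- small_fracture_cohort(seed = 98, n = 100)
  cv1 <- cross_validate(co, "I-II", seed = 8)
  fold <- cv1[["I-II"]]$fold_assignment[co$phenotypes$subject_id]
  k <- 1L
  co2 <- co
  mut <- which(fold == k)
  co2$genotypes$dosage[mut, ] <- withr::with_seed(2, {
    matrix(sample(0:2, length(mut) * ncol(co$genotypes$dosage),
                  replace = TRUE), length(mut))
  })
  cv2 <- cross_validate(co2, "I-II", seed = 8)
  expect_identical(cv1[["I-II"]]$fold_grs[[k]], cv2[["I-II"]]$fold_grs[[k]])
  expect_equal(cv1[["I-II"]]$fold_models[[k]]$coefficients,
               cv2[["I-II"]]$fold_models[[k]]$coefficients)
})

test_that("linear CV records per-fold test MSE", {
  co <- small_bmd_cohort(seed = 99, n = 200)
  cv <- cross_validate(co, c("II-I", "II-III"), seed = 9)
  expect_length(cv[["II-I"]]$fold_mse, 10)
  expect_true(all(cv[["II-I"]]$fold_mse >= 0))
  expect_identical(cv[["II-I"]]$fold_assignment,
                   cv[["II-III"]]$fold_assignment)
})
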