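test_that("risk-allele orientation points every SNP toward risk", {
  set.seed(71)
  n <- 400
  d <- matrix(sample(0:2, n * 3, replace = TRUE), n, 3,
              dimnames = list(NULL, c("pos", "neg", "null")))
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * d[, "pos"] - 1.5 * d[, "neg"]))
  ori <- orient_risk_alleles(d, y, "fracture")
  expect_false(ori$flip[["pos"]])
  expect_true(ori$flip[["neg"]])
  # after orientation every marginal association is non-negative
  expect_true(all(cov(ori$dosage, y) >= 0))

  # bmd: a BMD-increasing allele must be flipped toward lower BMD
  bmd <- 1 + 0.3 * d[, "pos"] - 0.3 * d[, "neg"] + rnorm(n, 0, 0.1)
  orib <- orient_risk_alleles(d, bmd, "bmd")
  expect_true(orib$flip[["pos"]])
  expect_false(orib$flip[["neg"]])
  expect_true(all(cov(orib$dosage, bmd) <= 0))

  expect_error(orient_risk_alleles(d, rep(1, n), "fracture"), "constant")
})

test_that("orientation flags are an involution on dosages", {
  set.seed(72)
  d <- matrix(sample(0:2, 60, replace = TRUE), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  flip <- c(a = TRUE, b = FALSE, c = TRUE)
  expect_identical(apply_orientation(apply_orientation(d, flip), flip), d)
})

test_that("lasso at lambda = 0 equals ordinary least squares", {
  set.seed(73)
  x <- matrix(rnorm(120 * 6), 120, 6, dimnames = list(NULL, letters[1:6]))
  y <- drop(x %*% c(1, -0.5, 0.25, 0, 0, 2)) + rnorm(120, 0, 0.3)
  fit <- lasso_fit(x, y, lambda = 0, family = "gaussian")
  ols <- coef(lm(y ~ x))
  expect_equal(unname(fit$weights), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(ols[1]), tolerance = 1e-6)
})

test_that("lasso zeroes all weights at and beyond lambda_max", {
  set.seed(74)
  x <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, letters[1:5]))
  y <- x[, 1] + rnorm(100, 0, 0.5)
  n <- nrow(x)
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  xs <- sweep(sweep(x, 2, colMeans(x)), 2, sds, `/`)
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / n
  expect_identical(unname(lasso_fit(x, y, lmax)$weights), rep(0, 5))
  expect_identical(unname(lasso_fit(x, y, lmax * 2)$weights), rep(0, 5))
  # just inside lambda_max at least one weight wakes up
  expect_gt(sum(lasso_fit(x, y, lmax * 0.8)$weights != 0), 0)
})

test_that("lasso soft-thresholds on an orthonormal standardized design", {
  set.seed(75)
  n <- 64
  p <- 4
  # orthonormalise against the intercept too: columns mean 0, 1/n-var 1,
  # mutually orthogonal
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1]
  x <- q * sqrt(n)
  colnames(x) <- letters[1:p]
  stopifnot(max(abs(crossprod(x) / n - diag(p))) < 1e-8)
  y <- drop(x %*% c(0.9, -0.4, 0.1, 0)) + rnorm(n, 0, 0.2)
  b_ols <- drop(crossprod(x, y - mean(y))) / n
  for (lam in c(0.05, 0.2, 0.5)) {
    expected <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
    fit <- lasso_fit(x, y, lam)
    expect_equal(unname(fit$weights), unname(expected), tolerance = 1e-6)
  }
})

test_that("sparsity is non-increasing in the penalty", {
  set.seed(76)
  x <- matrix(rnorm(150 * 10), 150, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  y <- drop(x[, 1:3] %*% c(1, -1, 0.5)) + rnorm(150, 0, 0.8)
  lams <- seq(0.01, 0.8, length.out = 8)
  nz <- vapply(lams, function(l) sum(lasso_fit(x, y, l)$weights != 0),
               numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("penalty selection shrinks hard under a null signal", {
  picks <- vapply(1:10, function(seed) {
    x <- withr::with_seed(seed, matrix(rnorm(100 * 15), 100, 15))
    y <- withr::with_seed(seed + 1000, rnorm(100))
    lam <- choose_penalty(x, y, "gaussian", seed = seed)
    lmax <- max(abs(crossprod(scale(x), y - mean(y)))) / 100
    # position on the log grid from lmax down to lmax/1000
    (log(lam) - log(lmax * 0.001)) / (log(lmax) - log(lmax * 0.001))
  }, numeric(1))
  expect_gte(mean(picks > 0.5), 0.8)
})

test_that("penalty selection keeps a genuinely strong predictor", {
  kept <- vapply(1:5, function(seed) {
    x <- withr::with_seed(seed, matrix(rnorm(400 * 10), 400, 10,
                                       dimnames = list(NULL,
                                                       paste0("s", 1:10))))
    y <- withr::with_seed(seed + 500, drop(x[, 1] * 2 + rnorm(400, 0, 0.5)))
    lam <- choose_penalty(x, y, "gaussian", seed = seed)
    lasso_fit(x, y, lam)$weights[["s1"]] != 0
  }, logical(1))
  expect_true(all(kept))
})

test_that("GRS is the weighted risk-allele sum, linear and permutable", {
  m <- grs_model(c("a", "b", "c"), rep(FALSE, 3), c(0.2, -0.1, 0.3),
                 "bmd", penalty = 0.1)
  d <- matrix(c(0, 1, 2), 1, dimnames = list("s1", c("a", "b", "c")))
  expect_equal(unname(compute_grs(d, m)), 0.5)

  m0 <- grs_model(c("a", "b", "c"), rep(FALSE, 3), rep(0, 3), "bmd", 0.1)
  expect_equal(unname(compute_grs(d, m0)), 0)

  m2 <- grs_model(c("a", "b", "c"), rep(FALSE, 3), 2 * c(0.2, -0.1, 0.3),
                  "bmd", 0.1)
  expect_equal(compute_grs(d, m2), 2 * compute_grs(d, m))

  # permuting model and data together leaves scores unchanged
  perm <- c("c", "a", "b")
  mp <- grs_model(perm, rep(FALSE, 3), c(0.3, 0.2, -0.1), "bmd", 0.1)
  expect_equal(compute_grs(d[, perm, drop = FALSE], mp), compute_grs(d, m))

  expect_error(compute_grs(d[, 1:2, drop = FALSE], m), "SNP mismatch")
})

test_that("trained GRS depends only on its training rows", {
  co <- small_fracture_cohort(seed = 81, n = 120)
  d <- co$genotypes$dosage
  y <- co$phenotypes$fracture
  tr <- 1:80
  m1 <- train_grs(d[tr, ], y[tr], "fracture", seed = 9)
  d2 <- d
  d2[81:120, ] <- withr::with_seed(1, {
    matrix(sample(0:2, 40 * ncol(d), replace = TRUE), 40)
  })
  m2 <- train_grs(d2[tr, ], y[tr], "fracture", seed = 9)
  expect_identical(m1, m2)
})

test_that("GRS model serialization round-trips", {
  m <- grs_model(c("rs1", "rs2"), c(TRUE, FALSE), c(0.123456789, 0),
                 "fracture", penalty = 0.0123)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_grs_model(m, path)
  m2 <- read_grs_model(path)
  expect_equal(m2$weights, m$weights)
  expect_identical(m2$orientation, m$orientation)
  expect_identical(m2$trait_kind, m$trait_kind)
  expect_equal(m2$penalty, m$penalty)
})
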