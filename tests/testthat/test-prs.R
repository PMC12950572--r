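test_that("the design matrix applies the fixed standardization constants", {
  cfg <- simulationConfig(nSamples = 40, nVariants = 30, seed = 61)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  ph$age[1] <- 91.96
  ph$cholesterol[1] <- 6.22
  d <- buildDesign(gm, ph, gwasResults = NULL)
  expect_equal(ncol(d$X), 13)            # clinical-only design
  expect_equal(unname(d$X[1, "age"]), 0, tolerance = 1e-12)
  expect_equal(unname(d$X[1, "cholesterol"]), (6.22 - 4.92) / 1.30,
               tolerance = 1e-12)
  # binary flags pass through unstandardized
  expect_true(all(d$X[, "anemia"] %in% c(0, 1)))
  expect_true(all(d$X[, "gds5"] %in% 0:5))
})

test_that("selected variants enter the design as dosage columns", {
  cfg <- simulationConfig(nSamples = 150, nVariants = 100,
                          mafRange = c(0.3, 0.5), noiseSd = 2,
                          causal = data.frame(index = 7L, effect = -12),
                          fracMultiallelic = 0, seed = 62)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  res <- crossvalidatedGwas(gm, ph, folds = 5, frac = 0.8, seed = 62)
  d <- buildDesign(gm, ph, res, pThreshold = 1e-4)
  expect_gte(length(d$variantKeys), 1)
  expect_true(variantKeys(gm)[7] %in% d$variantKeys)
  expect_equal(ncol(d$X), 13 + length(d$variantKeys))
  # a selected key absent from the genotypes is an error
  tb <- gwasTable(res); tb$key[which.min(tb$pGeom)] <- "chrX:1:A:G"
  expect_error(buildDesign(gm, ph, tb, pThreshold = 1e-4), "absent")
})

test_that("ridge at lambda = 0 with full rank equals OLS", {
  set.seed(63)
  n <- 60; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  y <- 96.96 + 10.04 * rnorm(n)
  m <- fitPcaRidge(X, y, k = p, lambda = 0)
  ols <- lm.fit(cbind(1, X), (y - 96.96) / 10.04)
  predOls <- 96.96 + 10.04 * (cbind(1, X) %*% ols$coefficients)[, 1]
  expect_equal(predict(m, X), predOls, tolerance = 1e-8)
})

test_that("an overwhelming penalty collapses to the training mean", {
  set.seed(64)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- rnorm(50, 100, 8)
  m <- fitPcaRidge(X, y, k = 5, lambda = 1e12)
  expect_equal(predict(m, X), rep(mean(y), 50), tolerance = 1e-6)
})

test_that("closed-form ridge matches a gradient-descent oracle", {
  set.seed(65)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10, 97, 10)
  lam <- 3.7; k <- 5
  m <- fitPcaRidge(X, y, k = k, lambda = lam)
  ys <- (y - 96.96) / 10.04
  Xc <- sweep(X, 2, colMeans(X))
  V <- m@rotation
  Z <- Xc %*% V
  b <- ridgeGradientOracle(Z, ys - mean(ys), lam)
  expect_equal(m@coef, b, tolerance = 1e-6)
})

test_that("perturbing the ridge solution increases the penalized loss", {
  set.seed(66)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40, 97, 10)
  lam <- 2; k <- 4
  m <- fitPcaRidge(X, y, k = k, lambda = lam)
  ys <- (y - 96.96) / 10.04
  Z <- sweep(X, 2, colMeans(X)) %*% m@rotation
  loss <- function(b) sum((ys - mean(ys) - Z %*% b)^2) + lam * sum(b^2)
  L0 <- loss(m@coef)
  for (j in seq_len(k)) for (s in c(-1e-3, 1e-3)) {
    b <- m@coef; b[j] <- b[j] + s
    expect_gt(loss(b), L0)
  }
})

test_that("back-transformed coefficients reproduce projected predictions", {
  cfg <- simulationConfig(nSamples = 100, nVariants = 40, seed = 67)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  d <- buildDesign(gm, ph, gwasResults = NULL)
  m <- fitPcaRidge(d, ph$cr, k = 6, lambda = 10)
  raw <- as.matrix(ph[, m@featureNames])
  expect_equal(predict(m, raw, route = "raw"),
               predict(m, raw, route = "projected"), tolerance = 1e-10)
  # single feature, identity projection, no penalty -> the OLS slope
  x1 <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x"))
  yy <- rnorm(30, 97, 9)
  m1 <- fitPcaRidge(x1, yy, k = 1, lambda = 0)
  slope <- coef(lm(yy ~ x1))[[2]]
  expect_equal(unname(ridgeCoefficients(m1)[["x"]]), slope,
               tolerance = 1e-8)
  # a constant feature has zero loading, hence zero raw coefficient
  x2 <- cbind(a = rnorm(30), b = 1)
  m2 <- fitPcaRidge(x2, yy, k = 1, lambda = 1)
  expect_equal(ridgeCoefficients(m2)[["b"]], 0, tolerance = 1e-12)
})

test_that("k above the design rank is a singular-projection error", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fitPcaRidge(X, rnorm(20, 97, 10), k = 4, lambda = 1),
               "rank")
})

test_that("the hyperparameter grid is exhaustive and seed-stable", {
  set.seed(201)
  n <- 150; p <- 30
  L <- matrix(rnorm(n * 5), n, 5)
  X <- L %*% (matrix(rnorm(5 * p), 5, p) * 4) +
    matrix(rnorm(n * p, sd = 1), n, p)
  y <- 96.96 + 10.04 * (L %*% rep(0.5, 5))[, 1] + rnorm(n, sd = 3)
  m <- ridgeGridSearch(X, y, kRange = c(2, 12), seed = 1)
  expect_equal(nrow(m@grid), 11 * 13)     # |k grid| x |lambda grid|
  m2 <- ridgeGridSearch(X, y, kRange = c(2, 12), seed = 1)
  expect_identical(c(m@k, m@lambda), c(m2@k, m2@lambda))
  expect_gt(m@r2Train, 0.8)
})

test_that("five-component data concentrate the selected k near five", {
  ks <- vapply(1:5, function(s) {
    set.seed(200 + s)
    n <- 150; p <- 30
    L <- matrix(rnorm(n * 5), n, 5)
    X <- L %*% (matrix(rnorm(5 * p), 5, p) * 4) +
      matrix(rnorm(n * p, sd = 1), n, p)
    y <- 96.96 + 10.04 * (L %*% rep(0.5, 5))[, 1] + rnorm(n, sd = 3)
    ridgeGridSearch(X, y, kRange = c(2, 12), seed = s)@k
  }, 0L)
  expect_true(all(ks >= 5))        # never fewer than the true dimension
  expect_lte(median(ks), 8)        # and no systematic drift upward
})

test_that("k range wider than the feature count is truncated with warning", {
  X <- matrix(rnorm(200 * 8), 200, 8)
  y <- rnorm(200, 97, 10)
  expect_warning(m <- ridgeGridSearch(X, y, kRange = c(5, 55), seed = 2),
                 "truncated")
  expect_lte(m@k, 8)
})

test_that("rSquared follows its definition", {
  y <- c(1, 3, 5, 9)
  expect_equal(rSquared(y, y), 1)
  expect_equal(rSquared(y, rep(mean(y), 4)), 0)
  # hand computation: SS_res = 1+0+1+4 = 6, SS_tot = 35
  pred <- c(2, 3, 4, 7)
  expect_equal(rSquared(y, pred), 1 - 6 / 35)
  expect_error(rSquared(c(2, 2), c(1, 2)), "variance")
  expect_error(rSquared(1:3, 1:4), "length")
})

test_that("training R2 exceeds held-out R2 on noise-dominated data", {
  gaps <- vapply(1:5, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(100 * 20), 100, 20)
    y <- rnorm(100, 96.96, 10.04)
    m <- ridgeGridSearch(X, y, kRange = c(5, 15), seed = s)
    m@r2Train - m@r2Test
  }, 0)
  expect_gt(mean(gaps), 0)
})
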