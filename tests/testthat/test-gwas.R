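test_that("noiseless fits recover the exact slope", {
  set.seed(1)
  g <- rbinom(20, 2, 0.5)
  r <- fitVariantRegression(3 * g, g)
  expect_equal(r$beta, 3, tolerance = 1e-10)
  expect_lt(r$p, 1e-15)
})

test_that("OLS matches the normal-equations oracle with covariates", {
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(12:20, 1)
    C <- cbind(rnorm(n), rbinom(n, 1, 0.5))
    g <- rbinom(n, 2, 0.4)
    if (var(g) == 0) next
    y <- rnorm(n)
    r <- fitVariantRegression(y, g, C)
    o <- olsOracle(y, cbind(1, C, g))
    k <- length(o$beta)
    expect_equal(r$beta, o$beta[k], tolerance = 1e-10)
    expect_equal(r$se, o$se[k], tolerance = 1e-10)
    expect_equal(r$p, o$p[k], tolerance = 1e-10)
  }
})

test_that("missing dosages drop rows; constant dosage is skipped", {
  set.seed(3)
  g <- c(NA, rbinom(19, 2, 0.5))
  y <- rnorm(20)
  r <- fitVariantRegression(y, g)
  expect_equal(r$n, 19)
  o <- olsOracle(y[-1], cbind(1, g[-1]))
  expect_equal(r$beta, o$beta[2], tolerance = 1e-10)
  r0 <- fitVariantRegression(y, rep(1, 20))
  expect_true(is.na(r0$beta))
  expect_equal(r0$reason, "constant dosage")
})

test_that("single-GWAS p-values are approximately uniform under the null", {
  set.seed(4)
  n <- 200; m <- 2000
  dos <- matrix(rbinom(n * m, 2, runif(m, 0.1, 0.5)), m, n, byrow = FALSE)
  gm <- makeGenotypes(dos)
  ph <- makePheno(n, seed = 44)
  ph$cr <- rnorm(n, 100, 5)
  res <- crossvalidatedGwas(gm, ph, folds = 1, frac = 1, seed = 4)
  p <- gwasTable(res)$pGeom
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("folds = 1, frac = 1 reduces to a plain GWAS", {
  cfg <- simulationConfig(nSamples = 80, nVariants = 60,
                          fracMultiallelic = 0, seed = 12)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  pcs <- genotypePCA(gm, k = 5)
  res <- crossvalidatedGwas(gm, ph, pcs, folds = 1, frac = 1, seed = 1,
                            nPcs = 5)
  tb <- gwasTable(res)
  C <- cbind(ph$age, ph$sex, ph$education, ph$interval, pcScores(pcs))
  for (j in c(1, 17, 42)) {
    r <- fitVariantRegression(ph$cr, dosages(gm)[j, ], C)
    i <- match(variantKeys(gm)[j], tb$key)
    expect_equal(tb$betaMean[i], r$beta, tolerance = 1e-10)
    expect_equal(tb$pGeom[i], r$p, tolerance = 1e-10)
  }
})

test_that("p-value aggregation follows the geometric-mean identities", {
  expect_equal(geometricMeanP(rep(0.01, 5)), 0.01)
  expect_equal(geometricMeanP(c(1e-2, 1e-4)), 1e-3)
  expect_equal(geometricMeanP(c(0.2, NA, 0.2)), 0.2)
  expect_true(is.na(geometricMeanP(c(NA_real_, NA_real_))))
  # underflow-proof in log space
  expect_equal(geometricMeanP(c(1e-300, 1e-100)), 1e-200)
})

test_that("geometric mean never exceeds the arithmetic mean across folds", {
  cfg <- simulationConfig(nSamples = 100, nVariants = 150,
                          fracMultiallelic = 0, seed = 14)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  res <- crossvalidatedGwas(gm, ph, folds = 5, frac = 0.8, seed = 14)
  tb <- gwasTable(res)
  pf <- sapply(gwasFolds(res), function(f) f$p[match(tb$key, f$key)])
  am <- rowMeans(pf, na.rm = TRUE)
  expect_true(all(tb$pGeom <= am + 1e-12))
  # identical sub-cohorts give identical fold p-values, so mean = each
  res1 <- crossvalidatedGwas(gm, ph, folds = 3, frac = 1, seed = 2)
  tb1 <- gwasTable(res1)
  p1 <- gwasFolds(res1)[[1]]$p[match(tb1$key, gwasFolds(res1)[[1]]$key)]
  expect_equal(tb1$pGeom, p1, tolerance = 1e-12)
})

test_that("fold membership and results are seed-deterministic", {
  cfg <- simulationConfig(nSamples = 90, nVariants = 80,
                          fracMultiallelic = 0, seed = 19)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  a <- crossvalidatedGwas(gm, ph, folds = 5, frac = 0.8, seed = 77)
  b <- crossvalidatedGwas(gm, ph, folds = 5, frac = 0.8, seed = 77)
  expect_identical(a@foldSamples, b@foldSamples)
  expect_identical(gwasTable(a), gwasTable(b))
  c <- crossvalidatedGwas(gm, ph, folds = 5, frac = 0.8, seed = 78)
  expect_false(identical(a@foldSamples, c@foldSamples))
})

test_that("tiers and selection respect strict thresholds", {
  tb <- data.frame(key = c("a", "b", "c"), chrom = "chr1", pos = 1:3,
                   ref = "A", alt = "G",
                   betaMean = c(-30, -20, 1),
                   pGeom = c(5.0e-8, 4.9e-8, 0.2),
                   nFolds = 5L, tier = c("sub_significant", "significant",
                                         "none"))
  sel <- selectSignificant(tb, 5e-8)
  expect_equal(sel$key, "b")               # 5.0e-8 exactly is excluded
  expect_equal(nrow(selectSignificant(tb[0, ], 5e-8)), 0)
  sub <- selectSignificant(tb, 5e-7)
  expect_equal(sub$key, c("b", "a"))       # sorted ascending by p
})

test_that("too-small folds are rejected", {
  cfg <- simulationConfig(nSamples = 20, nVariants = 10,
                          fracMultiallelic = 0, seed = 1)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  pcs <- genotypePCA(gm, k = 10)
  expect_error(
    crossvalidatedGwas(gm, ph, pcs, folds = 5, frac = 0.5, seed = 1),
    "too small")
})

test_that("manhattanQQ writes deterministic plot data and the lambda", {
  cfg <- simulationConfig(nSamples = 100, nVariants = 200,
                          fracMultiallelic = 0, seed = 23)
  gm <- simulateGenotypes(cfg)
  ph <- simulatePhenotypes(gm, cfg)
  res <- crossvalidatedGwas(gm, ph, folds = 5, frac = 0.8, seed = 23)
  pre <- file.path(tempdir(), "gwasplots")
  out <- suppressMessages(manhattanQQ(res, pre))
  expect_true(file.exists(paste0(pre, "_manhattan.tsv")))
  expect_true(file.exists(paste0(pre, "_qq.png")))
  expect_equal(out$lambdaAggregated, genomicInflation(gwasTable(res)$pGeom))
  expect_equal(out$lambda,
               median(sapply(gwasFolds(res), function(f)
                 genomicInflation(f$p))))
  man1 <- readLines(paste0(pre, "_manhattan.tsv"))
  out2 <- suppressMessages(manhattanQQ(res, pre))
  expect_identical(readLines(paste0(pre, "_manhattan.tsv")), man1)
})
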