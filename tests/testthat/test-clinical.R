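test_that("odds ratios and Wald CIs match published worked examples", {
  # printed (log-odds, SE) pairs reproduce the printed OR (95% CI)
  expect_equal(unname(round(oddsRatioCI(1.03, 0.49), 2)),
               c(2.80, 1.07, 7.32))      # depression
  expect_equal(unname(round(oddsRatioCI(-1.42, 0.50), 2)),
               c(0.24, 0.09, 0.64))      # hobby
  expect_equal(unname(round(oddsRatioCI(0.48, 0.21), 2)),
               c(1.62, 1.07, 2.44))      # total cholesterol
  expect_equal(unname(oddsRatioCI(0, 1)),
               exp(c(0, -1, 1) * qnorm(0.975)), tolerance = 1e-12)
  expect_equal(oddsRatioCI(0, 5)[["or"]], 1)
  expect_error(oddsRatioCI(1, 0), "se")
})

test_that("screening linear model recovers a planted anemia effect", {
  cfg <- simulationConfig(nSamples = 200, seed = 41, nVariants = 10,
                          covariateEffects = c(anemia = -4))
  ph <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
  rec <- fitLinearCR(ph, "anemia")
  expect_lt(abs(rec$beta - (-4)), 2 * rec$se)
  expect_lt(rec$p, 0.05)
})

test_that("linear fits agree with the normal-equations oracle", {
  ph <- makePheno(30, seed = 5)
  ph <- annotateCognition(ph)
  rec <- fitLinearCR(ph, "anemia")
  X <- cbind(1, ph$anemia, ph$age, ph$sex, ph$mmse_baseline, ph$interval)
  o <- olsOracle(ph$cr, X)
  expect_equal(rec$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(rec$se, o$se[2], tolerance = 1e-8)
  expect_equal(rec$p, o$p[2], tolerance = 1e-8)
})

test_that("a predictor collinear with protected covariates errors", {
  ph <- annotateCognition(makePheno(30, seed = 6))
  ph$age_copy <- ph$age
  expect_error(fitLinearCR(ph, "age_copy"), "aliased|collinear")
  expect_error(fitLinearCR(ph, "age"), "protected")
  ph$const <- 1
  expect_error(fitLinearCR(ph, "const"), "constant")
})

test_that("backward elimination keeps true effects, drops noise, never
           touches protected covariates", {
  cfg <- simulationConfig(nSamples = 200, seed = 43, nVariants = 10,
                          noiseSd = 3,
                          covariateEffects = c(anemia = -9))
  ph <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
  cand <- c("anemia", "pet", "hobby", "walking", "living_alone")
  mod <- backwardEliminateLinear(ph, cand)
  expect_true("anemia" %in% mod$retained)
  prot <- c("age", "sex", "mmse_baseline", "interval")
  expect_true(all(prot %in% mod$table$term))
  expect_true(all(mod$table$p[mod$table$term %in% mod$retained] < 0.05))
  # deterministic under identical input
  mod2 <- backwardEliminateLinear(ph, cand)
  expect_identical(mod$retained, mod2$retained)
  expect_identical(mod$dropped, mod2$dropped)
  # diagnostics are returned for residual inspection
  expect_equal(length(mod$residuals), length(mod$fitted))
  # empty candidate set yields the covariate-only model
  mod0 <- backwardEliminateLinear(ph, character(0))
  expect_equal(sort(mod0$table$term),
               sort(c("(Intercept)", prot)))
})

test_that("logistic progression fit matches the Newton oracle", {
  set.seed(51)
  n <- 150
  ph <- makePheno(n, seed = 51)
  ph$mmse_baseline <- sample(25:27, n, TRUE)       # everyone MCI
  ph <- annotateCognition(ph)
  lin <- -1 + 1.2 * ph$hobby + 0.05 * (ph$age - 92)
  ph$progression <- rbinom(n, 1, plogis(lin))
  rec <- fitLogisticProgression(ph, "hobby")
  X <- cbind(1, ph$hobby, ph$age, ph$sex, ph$interval)
  o <- logisticOracle(ph$progression, X)
  expect_equal(rec$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(rec$se, o$se[2], tolerance = 1e-6)
  expect_equal(rec$or, exp(o$beta[2]), tolerance = 1e-8)
})

test_that("a planted progression log-odds of 1 is recovered within 2 SE", {
  set.seed(52)
  n <- 500
  ph <- makePheno(n, seed = 52)
  ph$mmse_baseline <- sample(25:27, n, TRUE)
  ph <- annotateCognition(ph)
  ph$progression <- rbinom(n, 1, plogis(-0.5 + 1.0 * ph$depression))
  rec <- fitLogisticProgression(ph, "depression")
  expect_lt(abs(rec$beta - 1.0), 2 * rec$se)
  expect_false(rec$unstable)
})

test_that("logistic backward elimination drops by likelihood-ratio tests", {
  set.seed(53)
  n <- 400
  ph <- makePheno(n, seed = 53)
  ph$mmse_baseline <- sample(25:27, n, TRUE)
  ph <- annotateCognition(ph)
  lin <- -1 + 1.1 * ph$depression + 0.9 * (ph$cholesterol > 6) -
    1.2 * ph$hobby
  ph$progression <- rbinom(n, 1, plogis(lin))
  mod <- backwardEliminateLogistic(
    ph, c("depression", "hobby", "pet", "walking", "living_alone"))
  expect_true(all(c("depression", "hobby") %in% mod$retained))
  expect_true(all(c("age", "sex", "interval") %in% mod$table$term))
  expect_true(all(c("or", "ci_low", "ci_high") %in% colnames(mod$table)))
  expect_true(all(mod$table$ci_low <= mod$table$or &
                  mod$table$or <= mod$table$ci_high))
  # LRT p equals the chi-square tail of twice the log-likelihood drop
  full <- mod$model
  red <- update(full, . ~ . - depression, data = mod$data)
  pManual <- pchisq(2 * (as.numeric(logLik(full)) -
                         as.numeric(logLik(red))), 1, lower.tail = FALSE)
  dr <- drop1(full, scope = ~depression, test = "LRT")
  expect_equal(dr[["Pr(>Chi)"]][2], pManual, tolerance = 1e-8)
})

test_that("progression rates partition consistently", {
  ph <- makePheno(60, seed = 54)
  ph$mmse_baseline <- 26                            # all MCI at baseline
  ph <- annotateCognition(ph)
  ph$flag <- rep(c(0, 1), 30)
  rt <- progressionRates(ph, "flag")
  expect_equal(rt$n, c(30L, 30L))
  overall <- 100 * mean(ph$progression)
  pooled <- sum(rt$rate_percent * rt$n) / sum(rt$n)
  expect_equal(pooled, overall, tolerance = 1e-10)
  ph$always <- 1
  expect_warning(rt2 <- progressionRates(ph, "always"), "empty stratum")
  expect_true(is.na(rt2$rate_percent[1]))
  # a 10-of-20 stratum reads 50% (its complement stratum is empty)
  ph2 <- ph[1:20, ]; ph2$grp <- 1
  ph2$progression <- rep(c(0L, 1L), 10)
  expect_warning(rt3 <- progressionRates(ph2, "grp"), "empty stratum")
  expect_equal(rt3$rate_percent[2], 50)
})
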