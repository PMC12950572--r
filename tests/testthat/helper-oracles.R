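# Independent oracles and tiny fixtures shared across the test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact HWE null by direct log-factorial enumeration over all heterozygote
# counts compatible with the observed allele totals.
hweOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    a <- (rare - h) / 2
    b <- n - h - a
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 0)
  pr <- exp(logp)
  pObs <- pr[match(nAa, hs)]
  min(1, sum(pr[pr <= pObs * (1 + 1e-12)]))
}

# OLS through the normal equations (no QR), with t-test p-values.
olsOracle <- function(y, X) {
  XtXi <- solve(crossprod(X))
  beta <- unname(drop(XtXi %*% crossprod(X, y)))
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  se <- unname(sqrt(diag(XtXi) * sum(res^2) / df))
  t <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(t), df))
}

# Logistic regression by direct Newton iteration on the log-likelihood,
# run to gradient < 1e-12; standard errors from the observed information.
logisticOracle <- function(y, X, maxit = 200) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    g <- crossprod(X, y - mu)
    if (max(abs(g)) < 1e-12) break
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X)
    b <- b + drop(solve(H, g))
  }
  mu <- 1 / (1 + exp(-drop(X %*% b)))
  se <- unname(sqrt(diag(solve(crossprod(X * (mu * (1 - mu)), X)))))
  ll <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(beta = unname(b), se = se, logLik = ll)
}

# Ridge in a projected design by plain gradient descent on the stated
# penalized squared-error loss (intercept handled by centering).
ridgeGradientOracle <- function(Z, yc, lambda, iters = 2e5) {
  b <- rep(0, ncol(Z))
  L <- 2 * (svd(Z)$d[1]^2 + lambda)      # Lipschitz constant of the gradient
  for (i in seq_len(iters)) {
    grad <- -2 * crossprod(Z, yc - Z %*% b) + 2 * lambda * b
    b <- b - drop(grad) / L
  }
  b
}

# Hand-built GenotypeMatrix from a dosage matrix (variants x samples).
makeGenotypes <- function(dos, multi = rep(FALSE, nrow(dos))) {
  nv <- nrow(dos)
  alt <- lapply(seq_len(nv), function(j) if (multi[j]) c("G", "T") else "G")
  GenotypeMatrix(dos, chrom = rep("chr1", nv),
                 pos = seq_len(nv) * 100L, ref = rep("A", nv), alt = alt,
                 sampleIds = sprintf("s%03d", seq_len(ncol(dos))))
}

# Small VCF text fixture exercising phasing, missingness and multiallelics.
writeTinyVcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A", "B", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", ".", ".", "GT", "0/0",
          "0/1", sep = "\t"),
    paste("chr1", "200", ".", "T", "C,G", ".", ".", ".", "GT", "1/2",
          "0|1", sep = "\t"),
    paste("chr2", "300", ".", "G", "A", ".", ".", ".", "GT", "./.", "1/1",
          sep = "\t"),
    paste("chr2", "400", ".", "G", "A", ".", ".", ".", "GT", "./1", "0/0",
          sep = "\t")), path)
  path
}

# Minimal valid phenotype table (n rows) with every clinical column used
# by the models and the polygenic design.
makePheno <- function(n = 6, seed = 99) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    age = round(rnorm(n, 92, 2), 1),
    sex = rbinom(n, 1, 0.17),
    education = sample(0:2, n, TRUE),
    mmse_baseline = sample(25:30, n, TRUE),
    mmse_followup = sample(20:30, n, TRUE),
    interval = round(runif(n, 1.5, 2.5), 2),
    gds5 = sample(0:5, n, TRUE),
    anemia = rbinom(n, 1, 0.2), pet = rbinom(n, 1, 0.3),
    hearing_loss = rbinom(n, 1, 0.3),
    mobility_limited = rbinom(n, 1, 0.25), walking = rbinom(n, 1, 0.6),
    hobby = rbinom(n, 1, 0.5), living_alone = rbinom(n, 1, 0.4),
    bmi = round(rnorm(n, 24, 4), 1),
    cholesterol = round(rnorm(n, 4.9, 1.2), 2),
    glucose = round(rnorm(n, 5.4, 1.5), 2),
    ldl = round(rnorm(n, 3, 1), 2),
    quality_of_life = sample(0:10, n, TRUE))
}
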