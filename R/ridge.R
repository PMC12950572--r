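#' Training-set standardization constants for the polygenic model
#'
#' Fixed means and SDs used to standardize the five continuous clinical
#' features (age, baseline MMSE, BMI, glucose, total cholesterol) and the
#' CR outcome (mean 96.96, SD 10.04). Binary and ordinal features pass
#' through unstandardized.
#'
#' @return list with \code{features} (data.frame: feature, mean, sd) and
#'   \code{outcome} (named numeric mu, sigma).
#' @export
prsStandardization <- function() {
  list(features = data.frame(
         feature = c("age", "mmse_baseline", "bmi", "glucose",
                     "cholesterol"),
         mean = c(91.96, 25.63, 23.90, 5.42, 4.92),
         sd = c(2.06, 2.67, 8.77, 1.54, 1.30)),
       outcome = c(mu = 96.96, sigma = 10.04))
}

.prsClinical <- c("mmse_baseline", "gds5", "pet", "hearing_loss",
                  "mobility_limited", "walking", "quality_of_life", "bmi",
                  "anemia", "cholesterol", "glucose", "age", "sex")

#' Build the polygenic design matrix
#'
#' Columns are the risk-allele (alternate-allele) dosages of every variant
#' with averaged GWAS p below \code{pThreshold} (significant and
#' sub-significant hits), followed by the clinical predictors: baseline
#' MMSE, GDS-5 score, pet ownership, hearing loss, limited mobility,
#' walking, quality of life, BMI, anemia, total cholesterol, glucose, and
#' the age and sex adjustment. Continuous features are standardized with
#' the fixed training constants of \code{\link{prsStandardization}};
#' binary/ordinal features enter as 0/1 (or raw ordinal) codes. Missing
#' dosages are imputed with the variant mean.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param phenotypes phenotype data.frame in matching sample order.
#' @param gwasResults a \linkS4class{GwasResult} (or its table), or NULL
#'   for a clinical-only design.
#' @param pThreshold inclusion threshold on the averaged p (default 5e-7).
#' @return list of class \code{prsDesign}: \code{X} (standardized design),
#'   \code{center}, \code{scale} (per-column constants; 0/1 where
#'   unstandardized), \code{variantKeys}.
#' @export
buildDesign <- function(genotypes, phenotypes, gwasResults = NULL,
                        pThreshold = 5e-7) {
  miss <- setdiff(.prsClinical, colnames(phenotypes))
  if (length(miss))
    stop("phenotypes missing column(s): ", paste(miss, collapse = ", "))
  Xg <- NULL; keys <- character()
  if (!is.null(gwasResults)) {
    sel <- selectSignificant(gwasResults, pThreshold)
    if (nrow(sel)) {
      keys <- sel$key
      idx <- match(keys, variantKeys(genotypes))
      if (anyNA(idx))
        stop("selected variant(s) absent from genotype matrix: ",
             paste(keys[is.na(idx)], collapse = ", "))
      Xg <- t(dosages(genotypes)[idx, , drop = FALSE])
      for (j in seq_len(ncol(Xg))) {
        nas <- is.na(Xg[, j])
        if (any(nas)) Xg[nas, j] <- mean(Xg[, j], na.rm = TRUE)
      }
      colnames(Xg) <- keys
    }
  }
  Xc <- as.matrix(phenotypes[, .prsClinical])
  X <- if (is.null(Xg)) Xc else cbind(Xg, Xc)
  std <- prsStandardization()$features
  center <- stats::setNames(rep(0, ncol(X)), colnames(X))
  scl <- stats::setNames(rep(1, ncol(X)), colnames(X))
  for (i in seq_len(nrow(std))) {
    f <- std$feature[i]
    center[f] <- std$mean[i]
    scl[f] <- std$sd[i]
  }
  X <- sweep(sweep(X, 2, center), 2, scl, "/")
  structure(list(X = X, center = center, scale = scl, variantKeys = keys),
            class = "prsDesign")
}

#' PCA-projected ridge regression of CR
#'
#' The standardized outcome (CR - 96.96) / 10.04 is regressed on the
#' first \code{k} principal components of the (column-centered)
#' standardized design, minimizing the penalized squared error
#' sum((y - yhat)^2) + lambda * sum(beta^2) over the projected
#' coefficients; the intercept is unpenalized. The solution is closed
#' form. Coefficients are reverse-transformed through the projection and
#' the standardizations so predictions can be written as
#' CR = intercept + sum(coef_j * raw_feature_j); both prediction routes
#' agree to numerical precision.
#'
#' @param design a \code{prsDesign} from \code{\link{buildDesign}}, or a
#'   plain numeric matrix of (already standardized) features.
#' @param y raw CR values (percent).
#' @param k number of principal-component projections.
#' @param lambda ridge penalty (>= 0).
#' @return a \linkS4class{RidgeModel} (r2Test is NA until evaluated).
#' @export
fitPcaRidge <- function(design, y, k, lambda) {
  if (inherits(design, "prsDesign")) {
    X <- design$X; center <- design$center; scl <- design$scale
  } else {
    X <- as.matrix(design)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    center <- stats::setNames(rep(0, ncol(X)), colnames(X))
    scl <- stats::setNames(rep(1, ncol(X)), colnames(X))
  }
  stopifnot(length(y) == nrow(X), lambda >= 0, k >= 1)
  out <- prsStandardization()$outcome
  ys <- (y - out[["mu"]]) / out[["sigma"]]
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  if (k > rank)
    stop("singular projection: k = ", k, " exceeds rank ", rank)
  V <- sv$v[, seq_len(k), drop = FALSE]
  dk <- sv$d[seq_len(k)]
  m <- mean(ys)
  # in the principal basis Z = U diag(d): ridge is diagonal
  uy <- crossprod(sv$u[, seq_len(k), drop = FALSE], ys - m)[, 1]
  beta <- dk * uy / (dk^2 + lambda)
  intercept <- m
  fitted <- intercept + (Xc %*% V %*% beta)[, 1]
  r2 <- rSquared(ys, fitted)
  # back-transform: standardized-feature coefficients, then raw scale
  bStd <- (V %*% beta)[, 1]
  cRaw <- out[["sigma"]] * bStd / scl
  i0 <- out[["mu"]] + out[["sigma"]] *
    (intercept - sum(bStd * (center / scl + xm)))
  methods::new("RidgeModel",
    featureNames = colnames(X), featureCenter = center, featureScale = scl,
    yCenter = out[["mu"]], yScale = out[["sigma"]], trainCenter = xm,
    rotation = V, coef = beta, intercept = intercept, lambda = lambda,
    k = as.integer(k),
    coefRaw = stats::setNames(c(i0, cRaw),
                              c("(Intercept)", colnames(X))),
    r2Train = r2, r2Test = NA_real_, grid = data.frame())
}

#' Predict CR from a fitted ridge model
#'
#' \code{route = "raw"} uses the back-transformed per-feature
#' coefficients on raw features; \code{route = "projected"} standardizes,
#' centers and projects through the stored principal components. The two
#' agree to numerical precision.
#'
#' @param object a \linkS4class{RidgeModel}.
#' @param newdata matrix or data.frame with the model's feature columns,
#'   on the raw scale.
#' @param route "raw" or "projected".
#' @return numeric CR predictions (percent).
#' @export
setMethod("predict", "RidgeModel",
  function(object, newdata, route = c("raw", "projected")) {
    route <- match.arg(route)
    X <- as.matrix(newdata)
    if (is.null(colnames(X))) {
      if (ncol(X) != length(object@featureNames))
        stop("newdata must carry the model's ", length(object@featureNames),
             " feature columns")
      colnames(X) <- object@featureNames
    }
    X <- X[, object@featureNames, drop = FALSE]
    if (route == "raw") {
      cf <- object@coefRaw
      return(cf[1] + (X %*% cf[-1])[, 1])
    }
    Xs <- sweep(sweep(X, 2, object@featureCenter), 2,
                object@featureScale, "/")
    Xc <- sweep(Xs, 2, object@trainCenter)
    ys <- object@intercept + (Xc %*% object@rotation %*% object@coef)[, 1]
    object@yCenter + object@yScale * ys
  })

#' Exhaustive hyperparameter search for the polygenic ridge model
#'
#' Splits samples into train/test (default 80/20), enumerates every
#' combination of integer projection counts in \code{kRange} (truncated
#' to the training design's rank, with a warning) and ridge penalties in
#' \code{lambdaGrid} (default 13 log-spaced points spanning 1e-3 to 1e3),
#' fits on the training set and selects the combination with the highest
#' held-out R-squared (ties: fewer projections, then smaller lambda). The
#' winning model is refit on the training set and reported with both
#' R-squared values and the full grid.
#'
#' @param design \code{prsDesign} or matrix (see
#'   \code{\link{fitPcaRidge}}).
#' @param y raw CR values.
#' @param kRange integer range of projection counts (default 5 to 55).
#' @param lambdaGrid ridge penalties (default \code{10^seq(-3, 3, 0.5)}).
#' @param split training fraction (default 0.8).
#' @param seed RNG seed for the split.
#' @return the selected \linkS4class{RidgeModel}, with \code{grid} holding
#'   one row per evaluated (k, lambda).
#' @export
ridgeGridSearch <- function(design, y, kRange = c(5, 55),
                            lambdaGrid = 10^seq(-3, 3, by = 0.5),
                            split = 0.8, seed = 1) {
  X <- if (inherits(design, "prsDesign")) design$X else as.matrix(design)
  n <- nrow(X)
  set.seed(seed)
  tr <- sort(sample(n, round(split * n)))
  te <- setdiff(seq_len(n), tr)
  Xtr <- X[tr, , drop = FALSE]
  xm <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2, xm)
  out <- prsStandardization()$outcome
  ys <- (y - out[["mu"]]) / out[["sigma"]]
  ytr <- ys[tr]; yte <- ys[te]
  sv <- svd(Xc)
  rank <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  kMax <- min(kRange[2], rank)
  if (kMax < kRange[2])
    warning("k range truncated at design rank ", rank)
  ks <- seq(max(1, kRange[1]), kMax)
  m <- mean(ytr)
  uy <- crossprod(sv$u, ytr - m)[, 1]
  Zte <- sweep(X[te, , drop = FALSE], 2, xm) %*% sv$v
  grid <- expand.grid(k = ks, lambda = lambdaGrid)
  grid$r2_test <- NA_real_
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; lam <- grid$lambda[i]
    dk <- sv$d[seq_len(k)]
    beta <- dk * uy[seq_len(k)] / (dk^2 + lam)
    pred <- m + (Zte[, seq_len(k), drop = FALSE] %*% beta)[, 1]
    grid$r2_test[i] <- rSquared(yte, pred)
  }
  best <- grid[order(-grid$r2_test, grid$k, grid$lambda), ][1, ]
  model <- fitPcaRidge(
    if (inherits(design, "prsDesign"))
      structure(list(X = Xtr, center = design$center,
                     scale = design$scale,
                     variantKeys = design$variantKeys),
                class = "prsDesign")
    else Xtr,
    y[tr], k = best$k, lambda = best$lambda)
  model@r2Test <- best$r2_test
  model@grid <- grid
  model
}

#' Coefficient of determination
#'
#' 1 - SS_res / SS_tot with SS_tot about the mean of \code{yTrue}; can be
#' negative on held-out data.
#'
#' @param yTrue,yPred numeric vectors of equal length >= 2.
#' @return R-squared.
#' @export
rSquared <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred) || length(yTrue) < 2)
    stop("need equal lengths >= 2")
  sst <- sum((yTrue - mean(yTrue))^2)
  if (sst == 0) stop("zero variance in yTrue")
  1 - sum((yTrue - yPred)^2) / sst
}

#' Back-transformed per-feature coefficient table
#'
#' @param model a \linkS4class{RidgeModel}.
#' @return data.frame: term, coefficient (raw CR-percent scale).
#' @export
backtransformCoefficients <- function(model) {
  data.frame(term = names(model@coefRaw),
             coefficient = unname(model@coefRaw))
}
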