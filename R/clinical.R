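#' Adjusted single-predictor linear model of CR
#'
#' Fits CR on one candidate predictor plus the protected covariates (age,
#' sex, baseline MMSE and the follow-up interval by default) by ordinary
#' least squares and reports the predictor's coefficient with its
#' two-sided t-test. This is the screening model: candidates significant
#' here feed the multivariable backward elimination.
#'
#' @param data phenotype data.frame with \code{cr} (see
#'   \code{\link{annotateCognition}}).
#' @param predictor name of the candidate column.
#' @param protected covariate names never dropped.
#' @return one-row data.frame: term, beta, se, t, p, n.
#' @export
fitLinearCR <- function(data, predictor,
                        protected = c("age", "sex", "mmse_baseline",
                                      "interval")) {
  if (!predictor %in% colnames(data)) stop("unknown predictor: ", predictor)
  if (predictor %in% protected)
    stop("predictor coincides with a protected covariate")
  cols <- c("cr", predictor, protected)
  d <- data[stats::complete.cases(data[, cols]), cols]
  if (stats::var(d[[predictor]]) == 0) stop("predictor is constant")
  if (nrow(d) <= length(cols)) stop("too few complete rows")
  fml <- stats::reformulate(c(predictor, protected), response = "cr")
  fit <- stats::lm(fml, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("predictor aliased with the protected covariates (collinear)")
  cf <- summary(fit)$coefficients
  data.frame(term = predictor, beta = cf[predictor, 1],
             se = cf[predictor, 2], t = cf[predictor, 3],
             p = cf[predictor, 4], n = nrow(d), row.names = NULL)
}

.eliminate <- function(fit, data, response, candidates, protected, alpha,
                       test) {
  dropped <- data.frame(term = character(), p = numeric())
  repeat {
    if (!length(candidates)) break
    dr <- stats::drop1(fit, scope = stats::reformulate(candidates),
                       test = test)
    pcol <- grep("^Pr\\(", colnames(dr), value = TRUE)
    p <- dr[[pcol]]
    names(p) <- rownames(dr)
    p <- p[candidates]
    worst <- p[p >= alpha]
    if (!length(worst) || all(is.na(worst))) break
    # largest p first; ties broken by term name order
    mx <- max(worst, na.rm = TRUE)
    out <- sort(names(worst)[abs(worst - mx) < 1e-12])[1]
    dropped <- rbind(dropped, data.frame(term = out, p = p[[out]]))
    candidates <- setdiff(candidates, out)
    fml <- stats::reformulate(c(protected, candidates), response = response)
    fit <- suppressWarnings(stats::update(fit, fml, data = data))
  }
  list(fit = fit, candidates = candidates, dropped = dropped)
}

#' Backward elimination for the multivariable linear CR model
#'
#' Starts from CR on all candidates plus protected covariates and
#' iteratively removes the candidate with the largest partial-F p-value at
#' or above \code{alpha} (one term per iteration, ties broken by term name
#' order) until every remaining candidate is significant. Protected
#' covariates are never dropped. Residual diagnostics (residuals and
#' fitted values) are returned for distribution and
#' residual-versus-fitted inspection.
#'
#' @param data phenotype data.frame with \code{cr}.
#' @param candidates character vector of candidate predictor columns.
#' @param alpha retention threshold (default 0.05).
#' @param protected covariates never dropped.
#' @return list with \code{model} (the final \code{lm}), \code{table}
#'   (term, beta, se, t, p for every coefficient), \code{retained},
#'   \code{dropped} (with elimination p-values), and \code{residuals} /
#'   \code{fitted} diagnostics.
#' @export
backwardEliminateLinear <- function(data, candidates, alpha = 0.05,
                                    protected = c("age", "sex",
                                                  "mmse_baseline",
                                                  "interval")) {
  candidates <- setdiff(candidates, protected)
  cols <- c("cr", protected, candidates)
  miss <- setdiff(cols, colnames(data))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, cols]), cols]
  fml <- stats::reformulate(c(protected, candidates), response = "cr")
  fit <- stats::lm(fml, data = d)
  res <- .eliminate(fit, d, "cr", candidates, protected, alpha, test = "F")
  fit <- res$fit
  stopifnot(all(protected %in% attr(stats::terms(fit), "term.labels")))
  cf <- summary(fit)$coefficients
  list(model = fit,
       table = data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                          t = cf[, 3], p = cf[, 4], row.names = NULL),
       retained = res$candidates, dropped = res$dropped,
       residuals = stats::residuals(fit), fitted = stats::fitted(fit),
       data = d)
}

#' Adjusted single-predictor logistic model of MCI-to-dementia progression
#'
#' Restricted to participants with MCI at baseline, the outcome being
#' dementia at follow-up. Maximum-likelihood logistic fit of the outcome
#' on the predictor plus protected covariates (age, sex and the
#' assessment interval); Wald z-test, odds ratio and 95% CI. Quasi-perfect
#' separation is flagged (\code{unstable = TRUE}) rather than silently
#' reported.
#'
#' @param data phenotype data.frame with \code{stage_baseline} and
#'   \code{progression} (see \code{\link{annotateCognition}}).
#' @param predictor candidate column name.
#' @param protected covariates never dropped (baseline MMSE is excluded by
#'   default).
#' @return one-row data.frame: term, beta, se, or, ci_low, ci_high, z, p,
#'   n, unstable.
#' @export
fitLogisticProgression <- function(data, predictor,
                                   protected = c("age", "sex", "interval")) {
  d <- data[data$stage_baseline == "mci", , drop = FALSE]
  cols <- c("progression", predictor, protected)
  miss <- setdiff(cols, colnames(d))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  d <- d[stats::complete.cases(d[, cols]), cols]
  if (stats::var(d[[predictor]]) == 0) stop("predictor is constant")
  fml <- stats::reformulate(c(predictor, protected),
                            response = "progression")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = d,
               control = stats::glm.control(epsilon = 1e-12)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(is.na(stats::coef(fit))))
    stop("predictor aliased with the protected covariates (collinear)")
  cf <- summary(fit)$coefficients
  b <- cf[predictor, 1]; s <- cf[predictor, 2]
  orci <- oddsRatioCI(b, s)
  unstable <- sep || abs(b) > 15
  data.frame(term = predictor, beta = b, se = s, or = orci[["or"]],
             ci_low = orci[["lo"]], ci_high = orci[["hi"]],
             z = cf[predictor, 3], p = cf[predictor, 4], n = nrow(d),
             unstable = unstable, row.names = NULL)
}

#' Backward elimination for the multivariable progression model
#'
#' As \code{\link{backwardEliminateLinear}} but for the logistic
#' progression model, dropping by likelihood-ratio tests: at each step the
#' candidate whose removal has the largest LRT p-value at or above
#' \code{alpha} is eliminated. The final coefficient table carries log
#' odds, Wald z, odds ratios and 95% CIs.
#'
#' @inheritParams fitLogisticProgression
#' @param candidates candidate predictor columns.
#' @param alpha retention threshold (default 0.05).
#' @return list with \code{model}, \code{table} (term, beta, se, or,
#'   ci_low, ci_high, z, p), \code{retained}, \code{dropped}.
#' @export
backwardEliminateLogistic <- function(data, candidates, alpha = 0.05,
                                      protected = c("age", "sex",
                                                    "interval")) {
  candidates <- setdiff(candidates, protected)
  d <- data[data$stage_baseline == "mci", , drop = FALSE]
  cols <- c("progression", protected, candidates)
  miss <- setdiff(cols, colnames(d))
  if (length(miss)) stop("unknown column(s): ", paste(miss, collapse = ", "))
  d <- d[stats::complete.cases(d[, cols]), cols]
  fml <- stats::reformulate(c(protected, candidates),
                            response = "progression")
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = d,
                                     control = stats::glm.control(
                                       epsilon = 1e-12)))
  res <- .eliminate(fit, d, "progression", candidates, protected, alpha,
                    test = "LRT")
  fit <- res$fit
  stopifnot(all(protected %in% attr(stats::terms(fit), "term.labels")))
  cf <- summary(fit)$coefficients
  ci <- t(vapply(seq_len(nrow(cf)),
                 function(i) oddsRatioCI(cf[i, 1], cf[i, 2]),
                 c(or = 0, lo = 0, hi = 0)))
  list(model = fit,
       table = data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2],
                          or = ci[, "or"], ci_low = ci[, "lo"],
                          ci_high = ci[, "hi"], z = cf[, 3], p = cf[, 4],
                          row.names = NULL),
       retained = res$candidates, dropped = res$dropped, data = d)
}

#' Odds ratio with Wald confidence interval
#'
#' exp(beta) with interval exp(beta +/- z se); z = 1.959964 at the default
#' 95% level.
#'
#' @param beta log-odds coefficient.
#' @param se its standard error (> 0).
#' @param level confidence level (default 0.95).
#' @return named numeric c(or, lo, hi).
#' @examples
#' round(oddsRatioCI(1.03, 0.49), 2)   # 2.80, 1.07, 7.32
#' round(oddsRatioCI(-1.42, 0.50), 2)  # 0.24, 0.09, 0.64
#' @export
oddsRatioCI <- function(beta, se, level = 0.95) {
  if (se <= 0) stop("se must be > 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(or = exp(beta), lo = exp(beta - z * se), hi = exp(beta + z * se))
}

#' Progression rate by level of a binary factor
#'
#' Fraction of MCI participants progressing to dementia within each level
#' of a binary factor, in percent. Empty strata yield NA with a warning.
#'
#' @param data phenotype data.frame (restricted internally to baseline
#'   MCI).
#' @param factor binary column name.
#' @return data.frame: level, n, n_progressed, rate_percent.
#' @export
progressionRates <- function(data, factor) {
  d <- data[data$stage_baseline == "mci", , drop = FALSE]
  if (!factor %in% colnames(d)) stop("unknown column: ", factor)
  out <- lapply(c(0, 1), function(lv) {
    dd <- d[!is.na(d[[factor]]) & d[[factor]] == lv, , drop = FALSE]
    if (!nrow(dd)) {
      warning("empty stratum ", factor, " = ", lv)
      return(data.frame(level = lv, n = 0L, n_progressed = 0L,
                        rate_percent = NA_real_))
    }
    data.frame(level = lv, n = nrow(dd),
               n_progressed = sum(dd$progression),
               rate_percent = 100 * mean(dd$progression))
  })
  do.call(rbind, out)
}
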