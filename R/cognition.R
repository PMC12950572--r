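#' MMSE staging
#'
#' Classifies a Mini-Mental State Examination score into the three cognitive
#' stages used throughout the pipeline: scores above 27 are normal
#' cognition, 25-27 mild cognitive impairment (MCI), and below 25 dementia.
#' Participants with dementia at baseline (MMSE < 25) are excluded from the
#' cohort at entry.
#'
#' @param score integer MMSE score(s) in [0, 30]; vectorized.
#' @return factor with levels \code{normal}, \code{mci}, \code{dementia}.
#' @examples
#' classifyMmse(c(28, 25, 24))
#' @export
classifyMmse <- function(score) {
  if (any(is.na(score)) || any(score != round(score)) ||
      any(score < 0) || any(score > 30))
    stop("MMSE scores must be integers in [0, 30]")
  out <- ifelse(score > 27, "normal", ifelse(score >= 25, "mci", "dementia"))
  factor(out, levels = c("normal", "mci", "dementia"))
}

#' Depression flag from the five-item Geriatric Depression Scale
#'
#' @param gds5 integer GDS-5 score(s) in [0, 5]; a score of 2 or more flags
#'   depression.
#' @return logical vector.
#' @examples
#' depressionFlag(c(1, 2, 5))
#' @export
depressionFlag <- function(gds5) {
  if (any(is.na(gds5)) || any(gds5 != round(gds5)) ||
      any(gds5 < 0) || any(gds5 > 5))
    stop("GDS-5 scores must be integers in [0, 5]")
  gds5 >= 2
}

#' Cognitive resilience (CR)
#'
#' CR is the percentage ratio of follow-up to baseline MMSE:
#' \code{100 * followup / baseline}. Values above 100 indicate improvement.
#' The raw ratio is the primary endpoint; the assessment interval is
#' adjusted for downstream by entering every model as a covariate. An
#' annualized variant, \code{100 + (CR - 100) / interval}, is available via
#' \code{annualize = TRUE} for sensitivity analyses.
#'
#' @param mmseBaseline integer baseline MMSE, must be >= 25 (dementia at
#'   entry is an exclusion criterion).
#' @param mmseFollowup integer follow-up MMSE in [0, 30].
#' @param interval follow-up interval in years; required when
#'   \code{annualize = TRUE}.
#' @param annualize logical; spread the deviation from 100 over the interval.
#' @return numeric CR in percent.
#' @examples
#' computeCR(27, 27)        # 100
#' computeCR(28, 14)        # 50
#' computeCR(25, 27)        # 108: improvement is allowed
#' @export
computeCR <- function(mmseBaseline, mmseFollowup, interval = NULL,
                      annualize = FALSE) {
  if (any(mmseBaseline < 25) || any(mmseBaseline > 30))
    stop("baseline MMSE must be in [25, 30]: dementia is excluded at entry")
  if (any(mmseFollowup < 0) || any(mmseFollowup > 30))
    stop("follow-up MMSE must be in [0, 30]")
  cr <- 100 * mmseFollowup / mmseBaseline
  if (annualize) {
    if (is.null(interval)) stop("interval required to annualize CR")
    if (any(interval <= 0)) stop("interval must be > 0")
    cr <- 100 + (cr - 100) / interval
  }
  cr
}

#' MCI-to-dementia progression outcome
#'
#' TRUE when a participant free of dementia at baseline is staged as
#' demented at follow-up.
#'
#' @param stageBaseline,stageFollowup stages from \code{\link{classifyMmse}}
#'   (character or factor); baseline dementia is an error (excluded
#'   population).
#' @return logical vector.
#' @export
progressionOutcome <- function(stageBaseline, stageFollowup) {
  stageBaseline <- as.character(stageBaseline)
  stageFollowup <- as.character(stageFollowup)
  ok <- c("normal", "mci", "dementia")
  if (!all(stageBaseline %in% ok) || !all(stageFollowup %in% ok))
    stop("unknown cognitive stage")
  if (any(stageBaseline == "dementia"))
    stop("baseline dementia is excluded from the cohort")
  stageFollowup == "dementia"
}

#' Annotate a phenotype table with derived cognitive variables
#'
#' Adds \code{cr}, \code{stage_baseline}, \code{stage_followup},
#' \code{depression} (from GDS-5) and \code{progression} (NA for
#' participants normal at baseline only in the sense that the event is
#' still defined; progression is dementia at follow-up for everyone
#' dementia-free at baseline).
#'
#' @param pheno phenotype data.frame with columns \code{mmse_baseline},
#'   \code{mmse_followup}, \code{gds5}.
#' @return the data.frame with derived columns appended.
#' @export
annotateCognition <- function(pheno) {
  pheno$cr <- computeCR(pheno$mmse_baseline, pheno$mmse_followup)
  pheno$stage_baseline <- as.character(classifyMmse(pheno$mmse_baseline))
  pheno$stage_followup <- as.character(classifyMmse(pheno$mmse_followup))
  pheno$depression <- as.integer(depressionFlag(pheno$gds5))
  pheno$progression <- as.integer(
    progressionOutcome(pheno$stage_baseline, pheno$stage_followup))
  pheno
}
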