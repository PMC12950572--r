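#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges colData
NULL

#' GenotypeMatrix: samples-by-variants alternate-allele dosage container
#'
#' A thin extension of \linkS4class{RangedSummarizedExperiment} holding one
#' assay, \code{"dosage"}: an integer matrix (variants in rows, samples in
#' columns) with entries in \{0, 1, 2\} counting alternate alleles, or
#' \code{NA} for missing calls. Variant metadata (chromosome, 1-based
#' position, id, reference allele, list of alternate alleles) live in the
#' \code{rowRanges}; per-sample metadata (e.g. simulated subpopulation
#' labels) in \code{colData}.
#'
#' Multiallelic records (more than one alternate allele) are retained on
#' import and flagged by \code{\link{isMultiallelic}}; variant QC removes
#' them before association testing.
#'
#' @seealso \code{\link{readGenotypeVcf}}, \code{\link{simulateGenotypes}},
#'   \code{\link{applyQC}}
#' @aliases GenotypeMatrix-class
#' @exportClass GenotypeMatrix
setClass("GenotypeMatrix", contains = "RangedSummarizedExperiment")

.validGenotypeMatrix <- function(object) {
  msg <- NULL
  if (!("dosage" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!is.numeric(d))
      msg <- c(msg, "dosage must be numeric")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  need <- c("ref", "alt")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste0("rowRanges mcols must contain: ",
                         paste(miss, collapse = ", ")))
  if (length(rr) && any(GenomicRanges::start(rr) < 1))
    msg <- c(msg, "variant positions must be >= 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypeMatrix", .validGenotypeMatrix)

#' QCMask: per-variant quality-control verdicts
#'
#' One status per variant, assigned in fixed order by \code{\link{applyQC}}:
#' \code{pass}, \code{fail_multiallelic}, \code{fail_hwe} (exact
#' Hardy-Weinberg p below threshold), \code{fail_af_high} (alternate-allele
#' frequency above threshold), \code{fail_maf} (minor allele frequency below
#' threshold), or \code{fail_all_missing}. Carries the per-variant HWE
#' p-value and allele frequencies alongside.
#'
#' @slot status factor of per-variant verdicts.
#' @slot hweP numeric exact-test HWE p-values (NA where not computed).
#' @slot af numeric alternate-allele frequencies.
#' @slot maf numeric minor-allele frequencies.
#' @slot variantKey character chrom:pos:ref:alt keys.
#' @slot thresholds named numeric vector of the filter thresholds used.
#' @aliases QCMask-class
#' @exportClass QCMask
setClass("QCMask",
  representation(status = "factor", hweP = "numeric", af = "numeric",
                 maf = "numeric", variantKey = "character",
                 thresholds = "numeric"))

.qcLevels <- c("pass", "fail_multiallelic", "fail_hwe", "fail_af_high",
               "fail_maf", "fail_all_missing")

.validQCMask <- function(object) {
  msg <- NULL
  n <- length(object@status)
  if (!identical(levels(object@status), .qcLevels))
    msg <- c(msg, "status levels mismatch")
  if (any(is.na(object@status)))
    msg <- c(msg, "every variant needs exactly one status")
  if (length(object@hweP) != n || length(object@af) != n ||
      length(object@maf) != n || length(object@variantKey) != n)
    msg <- c(msg, "slot lengths differ")
  fr <- c(object@af, object@maf)
  fr <- fr[!is.na(fr)]
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
}
setValidity("QCMask", .validQCMask)

#' PCResult: genotype principal components for stratification control
#'
#' @slot scores numeric matrix, samples by components; columns are the
#'   per-sample principal component scores used as GWAS covariates.
#' @slot varExplained numeric fractions of variance explained, non-increasing.
#' @slot k integer number of components retained.
#' @slot nVariantsUsed integer count of QC-passing variants the PCA used.
#' @aliases PCResult-class
#' @exportClass PCResult
setClass("PCResult",
  representation(scores = "matrix", varExplained = "numeric",
                 k = "integer", nVariantsUsed = "integer"))

.validPCResult <- function(object) {
  msg <- NULL
  if (ncol(object@scores) != object@k)
    msg <- c(msg, "score columns must equal k")
  if (length(object@varExplained) < object@k)
    msg <- c(msg, "varExplained shorter than k")
  ve <- object@varExplained
  if (length(ve) > 1 && any(diff(ve) > 1e-8))
    msg <- c(msg, "varExplained must be non-increasing")
  if (sum(ve) > 1 + 1e-8)
    msg <- c(msg, "varExplained must sum to <= 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("PCResult", .validPCResult)

#' GwasResult: cross-validated association results
#'
#' Per-variant arithmetic-mean regression coefficients, geometric-mean
#' p-values across sub-cohort folds, and a significance tier:
#' \code{significant} (averaged p below the genome-wide threshold, default
#' 5e-8), \code{sub_significant} (below the suggestive threshold, default
#' 5e-7, but not genome-wide), or \code{none}.
#'
#' @slot table data.frame with one row per tested variant: key, chrom, pos,
#'   ref, alt, betaMean, pGeom, nFolds, tier.
#' @slot folds list of per-fold data.frames (key, beta, se, p, n).
#' @slot foldSamples list of integer vectors: sample indices per fold.
#' @slot thresholds named numeric, significance thresholds used.
#' @slot skipped data.frame of variants untestable in every fold, with reason.
#' @aliases GwasResult-class
#' @exportClass GwasResult
setClass("GwasResult",
  representation(table = "data.frame", folds = "list", foldSamples = "list",
                 thresholds = "numeric", skipped = "data.frame"))

.validGwasResult <- function(object) {
  msg <- NULL
  tb <- object@table
  need <- c("key", "chrom", "pos", "ref", "alt", "betaMean", "pGeom",
            "nFolds", "tier")
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, "result table misses required columns")
  if (nrow(tb)) {
    p <- tb$pGeom
    if (any(!is.na(p) & (p <= 0 | p > 1)))
      msg <- c(msg, "averaged p-values must lie in (0, 1]")
    sig <- object@thresholds[["significant"]]
    sub <- object@thresholds[["sub_significant"]]
    want <- ifelse(p < sig, "significant",
                   ifelse(p < sub, "sub_significant", "none"))
    if (any(!is.na(p) & tb$tier != want))
      msg <- c(msg, "tier inconsistent with thresholds")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GwasResult", .validGwasResult)

#' RidgeModel: PCA-projected ridge model of cognitive resilience
#'
#' Stores everything needed to reproduce predictions on the raw feature
#' scale: the feature standardization constants, the outcome
#' standardization (mean and SD of CR in the training set), the retained
#' principal-component projection, the penalized coefficients in projected
#' space, and the back-transformed per-feature coefficients. Predictions
#' from the projected space and from the back-transformed coefficients
#' agree to numerical precision.
#'
#' @slot featureNames character, design-matrix column names (selected
#'   variant dosages then clinical features).
#' @slot featureCenter,featureScale named numeric standardization constants
#'   applied to the design columns (scale 1 for unstandardized columns).
#' @slot yCenter,yScale numeric outcome standardization constants.
#' @slot trainCenter named numeric column means of the standardized training
#'   design (removed before projection).
#' @slot rotation numeric matrix (features by k) of PCA loadings.
#' @slot coef numeric penalized coefficients in projected space.
#' @slot intercept numeric intercept in projected, standardized-outcome space.
#' @slot lambda,k the ridge penalty and number of projections.
#' @slot coefRaw named numeric per-feature coefficients on the raw scale,
#'   first element the intercept.
#' @slot r2Train,r2Test numeric coefficients of determination.
#' @slot grid data.frame of the hyperparameter search, if performed.
#' @aliases RidgeModel-class
#' @exportClass RidgeModel
setClass("RidgeModel",
  representation(featureNames = "character", featureCenter = "numeric",
                 featureScale = "numeric", yCenter = "numeric",
                 yScale = "numeric", trainCenter = "numeric",
                 rotation = "matrix", coef = "numeric",
                 intercept = "numeric", lambda = "numeric", k = "integer",
                 coefRaw = "numeric", r2Train = "numeric",
                 r2Test = "numeric", grid = "data.frame"))

.validRidgeModel <- function(object) {
  msg <- NULL
  if (ncol(object@rotation) != object@k)
    msg <- c(msg, "rotation must have k columns")
  if (length(object@coef) != object@k)
    msg <- c(msg, "coef must have length k")
  if (nrow(object@rotation) != length(object@featureNames))
    msg <- c(msg, "rotation rows must match features")
  if (object@lambda < 0)
    msg <- c(msg, "lambda must be >= 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("RidgeModel", .validRidgeModel)
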