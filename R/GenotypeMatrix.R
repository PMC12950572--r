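#' Construct a GenotypeMatrix
#'
#' @param dosage integer matrix, variants in rows and samples in columns,
#'   entries in \{0, 1, 2\} or NA (missing genotype).
#' @param chrom character chromosome per variant.
#' @param pos integer 1-based position per variant.
#' @param ref character reference allele per variant.
#' @param alt list (or \code{CharacterList}) of alternate alleles per
#'   variant; length > 1 marks a multiallelic record.
#' @param id character variant identifiers ("" if absent).
#' @param sampleIds character sample identifiers.
#' @param colData optional \code{DataFrame} of per-sample metadata.
#' @return A \linkS4class{GenotypeMatrix}.
#' @examples
#' gm <- GenotypeMatrix(matrix(c(0L, 1L), 1, 2), chrom = "chr1", pos = 100L,
#'                      ref = "A", alt = list("G"), sampleIds = c("s1", "s2"))
#' dosages(gm)
#' @export
GenotypeMatrix <- function(dosage, chrom, pos, ref, alt, id = NULL,
                           sampleIds = NULL, colData = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  nv <- nrow(dosage)
  if (length(chrom) != nv || length(pos) != nv || length(ref) != nv)
    stop("variant metadata length must match nrow(dosage)")
  if (is.null(id)) id <- rep("", nv)
  if (!methods::is(alt, "CharacterList")) alt <- IRanges::CharacterList(alt)
  if (length(alt) != nv) stop("alt list length must match nrow(dosage)")
  if (any(pos < 1)) stop("variant positions must be >= 1")
  if (is.null(sampleIds))
    sampleIds <- sprintf("S%03d", seq_len(ncol(dosage)))
  if (anyDuplicated(sampleIds)) stop("sample ids must be unique")
  rr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = ref, alt = alt, id = as.character(id))
  names(rr) <- paste0(chrom, ":", pos, ":", ref, ":",
                      vapply(alt, paste, "", collapse = ","))
  cd <- if (is.null(colData)) S4Vectors::DataFrame(row.names = sampleIds)
        else colData
  rownames(cd) <- sampleIds
  dimnames(dosage) <- list(names(rr), sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowRanges = rr, colData = cd)
  methods::new("GenotypeMatrix", se)
}

#' @rdname GenotypeMatrix
#' @param x A GenotypeMatrix.
#' @details \code{dosages} returns the variants-by-samples integer dosage
#'   matrix (alternate-allele counts, NA = missing call).
#' @export
dosages <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @rdname GenotypeMatrix
#' @details \code{variantKeys} returns chrom:pos:ref:alt keys.
#' @export
variantKeys <- function(x) rownames(x)

#' @rdname GenotypeMatrix
#' @details \code{isMultiallelic} flags variants with more than one
#'   alternate allele.
#' @export
isMultiallelic <- function(x) {
  lengths(S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$alt) > 1L
}

#' @rdname GenotypeMatrix
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dosages(object)
  cat("GenotypeMatrix:", ncol(d), "samples x", nrow(d), "variants\n")
  cat("  multiallelic:", sum(isMultiallelic(object)),
      " missing calls:", sum(is.na(d)), "\n")
  invisible(object)
})

setMethod("show", "QCMask", function(object) {
  cat("QCMask over", length(object@status), "variants\n")
  print(table(object@status))
  invisible(object)
})

setMethod("show", "PCResult", function(object) {
  cat("PCResult:", nrow(object@scores), "samples,", object@k,
      "components (", object@nVariantsUsed, "variants )\n")
  cat("  variance explained:",
      paste(sprintf("%.3f", utils::head(object@varExplained, 5)),
            collapse = " "), "...\n")
  invisible(object)
})

setMethod("show", "GwasResult", function(object) {
  tb <- object@table
  cat("GwasResult:", nrow(tb), "variants over", length(object@folds),
      "folds\n")
  cat("  significant:", sum(tb$tier == "significant"),
      " sub-significant:", sum(tb$tier == "sub_significant"), "\n")
  invisible(object)
})

setMethod("show", "RidgeModel", function(object) {
  cat("RidgeModel: k =", object@k, " lambda =", object@lambda, "\n")
  cat(sprintf("  R2 train = %.3f  R2 test = %.3f\n",
              object@r2Train, object@r2Test))
  invisible(object)
})

#' Accessors for QC, PCA, GWAS and ridge results
#'
#' \code{qcStatus}, \code{qcPass}, \code{hweP} and \code{alleleFreqs} read a
#' \linkS4class{QCMask}; \code{pcScores} and \code{pcVarExplained} read a
#' \linkS4class{PCResult}; \code{gwasTable} and \code{gwasFolds} read a
#' \linkS4class{GwasResult}; \code{ridgeCoefficients} reads a
#' \linkS4class{RidgeModel}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
qcStatus <- function(x) stats::setNames(as.character(x@status), x@variantKey)

#' @rdname accessors
#' @export
qcPass <- function(x) as.character(x@status) == "pass"

#' @rdname accessors
#' @export
hweP <- function(x) stats::setNames(x@hweP, x@variantKey)

#' @rdname accessors
#' @export
alleleFreqs <- function(x) data.frame(key = x@variantKey, af = x@af,
                                      maf = x@maf)

#' @rdname accessors
#' @export
pcScores <- function(x) x@scores

#' @rdname accessors
#' @export
pcVarExplained <- function(x) x@varExplained

#' @rdname accessors
#' @export
gwasTable <- function(x) x@table

#' @rdname accessors
#' @export
gwasFolds <- function(x) x@folds

#' @rdname accessors
#' @export
ridgeCoefficients <- function(x) x@coefRaw
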