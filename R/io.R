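#' Read diploid genotypes from a VCF file
#'
#' Parses the GT field (the only FORMAT field used) of a VCF v4.x file into
#' an alternate-allele dosage matrix. Phased separators ("|") are treated
#' like unphased ("/"). Fully or half-missing calls ("./.", ".", "./1")
#' become NA. Multiallelic records are retained with dosage counting any
#' non-reference allele; they are flagged and removed later by
#' \code{\link{applyQC}}. Non-diploid calls are an error.
#'
#' @param path VCF file (plain or gzip).
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeVcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || !("FORMAT" %in% colnames(gt)))
    stop("VCF parse error: no FORMAT/genotype columns in ", path)
  samples <- setdiff(colnames(gt), "FORMAT")
  gtIdx <- vapply(strsplit(gt[, "FORMAT"], ":", fixed = TRUE),
                  function(f) match("GT", f), 0L)
  if (any(is.na(gtIdx)))
    stop("VCF parse error: record without GT in FORMAT (line ",
         which(is.na(gtIdx))[1], " of body)")
  nv <- nrow(fix)
  dos <- matrix(NA_integer_, nv, length(samples))
  for (s in seq_along(samples)) {
    cell <- gt[, samples[s]]
    hasSub <- grepl(":", cell, fixed = TRUE)
    call <- cell
    if (any(hasSub, na.rm = TRUE)) {
      ii <- which(!is.na(cell) & hasSub)
      call[ii] <- mapply(function(x, k) strsplit(x, ":", fixed = TRUE)[[1]][k],
                         cell[ii], gtIdx[ii])
    }
    dos[, s] <- .gtToDosage(call, samples[s])
  }
  alt <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                  fixed = TRUE)
  GenotypeMatrix(dos,
                 chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]),
                 ref = fix[, "REF"], alt = alt,
                 id = ifelse(is.na(fix[, "ID"]), "", fix[, "ID"]),
                 sampleIds = samples)
}

.gtToDosage <- function(gtString, sample) {
  # parse each distinct genotype string once, then map
  u <- unique(gtString)
  ud <- vapply(u, function(g) {
    if (is.na(g) || g == "." || g == "./." || g == ".|.")
      return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2)
      stop("non-diploid genotype '", g, "' for sample ", sample)
    if (any(alleles == ".")) return(NA_integer_)   # half-missing
    a <- suppressWarnings(as.integer(alleles))
    if (any(is.na(a)) || any(a < 0))
      stop("malformed genotype '", g, "' for sample ", sample)
    sum(a > 0L)                          # count of non-reference alleles
  }, 0L)
  unname(ud[match(gtString, u)])
}

#' Write a GenotypeMatrix as VCF
#'
#' Emits a minimal VCFv4.2 with GT as the only FORMAT field. Missing
#' dosages are written as "./."; dosage 1 as "0/1" and dosage 2 as "1/1"
#' (for multiallelic records the first alternate allele carries the
#' dosage). Output is gzip-compressed when \code{path} ends in ".gz",
#' plain text otherwise.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGenotypeVcf <- function(genotypes, path) {
  rr <- SummarizedExperiment::rowRanges(genotypes)
  mc <- S4Vectors::mcols(rr)
  d <- dosages(genotypes)
  gtChar <- matrix("./.", nrow(d), ncol(d))
  gtChar[!is.na(d) & d == 0] <- "0/0"
  gtChar[!is.na(d) & d == 1] <- "0/1"
  gtChar[!is.na(d) & d == 2] <- "1/1"
  fix <- cbind(CHROM = as.character(GenomicRanges::seqnames(rr)),
               POS = as.character(GenomicRanges::start(rr)),
               ID = ifelse(mc$id == "", ".", mc$id),
               REF = as.character(mc$ref),
               ALT = vapply(mc$alt, paste, "", collapse = ","),
               QUAL = ".", FILTER = ".", INFO = ".")
  gt <- cbind(FORMAT = rep("GT", nrow(d)), gtChar)
  colnames(gt) <- c("FORMAT", colnames(d))
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(v, path)
  } else {
    tmp <- paste0(path, ".tmp.gz")
    on.exit(unlink(tmp), add = TRUE)
    vcfR::write.vcf(v, tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
  }
  invisible(path)
}

.phenoRequired <- c("sample_id", "age", "sex", "education", "mmse_baseline",
                    "mmse_followup", "interval", "gds5")

#' Read and validate a cohort phenotype table
#'
#' Tab- (or comma-) delimited text with a header. Required columns:
#' sample_id, age, sex (0 = female, 1 = male, or the strings
#' "female"/"male"), education (ordinal 0 = secondary or lower, 1 =
#' secondary and vocational, 2 = higher), mmse_baseline and mmse_followup
#' (integers in [0, 30]), interval (years, > 0), gds5 (0-5). Any further
#' columns (binary clinical/social flags, continuous biomarkers) pass
#' through untouched.
#'
#' @param path delimited file.
#' @param sep field separator (default tab).
#' @return validated data.frame.
#' @export
readPhenotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(.phenoRequired, colnames(df))
  if (length(miss))
    stop("phenotype table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (is.character(df$sex)) {
    if (!all(df$sex %in% c("female", "male")))
      stop("sex must be coded 0/1 or female/male")
    df$sex <- as.integer(df$sex == "male")
  }
  if (!all(df$sex %in% c(0, 1))) stop("sex must be coded 0/1 or female/male")
  if (!all(df$education %in% c(0, 1, 2)))
    stop("education must be ordinal 0, 1 or 2")
  for (col in c("mmse_baseline", "mmse_followup")) {
    x <- df[[col]]
    if (any(is.na(x)) || any(x < 0) || any(x > 30) || any(x != round(x)))
      stop(col, " must be integers in [0, 30]")
  }
  if (any(df$interval <= 0)) stop("interval must be > 0 years")
  if (any(df$gds5 < 0) || any(df$gds5 > 5))
    stop("gds5 must lie in [0, 5]")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  df
}

#' @rdname readPhenotypes
#' @param pheno phenotype data.frame.
#' @export
writePhenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read cross-validated GWAS results
#'
#' Tab-delimited, one row per variant in a stable column order (key, chrom,
#' pos, ref, alt, beta_mean, p_geom, n_folds, tier); p-values in scientific
#' notation with enough digits for a lossless (1e-12 relative) round trip.
#'
#' @param results a \linkS4class{GwasResult} or its table.
#' @param path output file.
#' @export
writeGwasResults <- function(results, path) {
  tb <- if (methods::is(results, "GwasResult")) results@table else results
  out <- data.frame(key = tb$key, chrom = tb$chrom, pos = tb$pos,
                    ref = tb$ref, alt = tb$alt,
                    beta_mean = sprintf("%.15g", tb$betaMean),
                    p_geom = sprintf("%.15e", tb$pGeom),
                    n_folds = tb$nFolds, tier = tb$tier)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGwasResults
#' @export
readGwasResults <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pos = "integer"))
  df$beta_mean <- as.numeric(df$beta_mean)
  df$p_geom <- as.numeric(df$p_geom)
  df
}
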