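#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test conditional on the observed allele counts: under the null the
#' heterozygote count follows the classical hypergeometric-type distribution
#' over all genotype configurations with the same allele totals, and the
#' p-value sums the probabilities of every heterozygote count no more
#' probable than the observed one. Probabilities are computed by the stable
#' mid-point recurrence, normalized over the full support; no mid-p
#' correction is applied. Monomorphic variants have a single attainable
#' configuration and return p = 1.
#'
#' @param nHomRef,nHet,nHomAlt non-negative genotype counts (reference
#'   homozygote, heterozygote, alternate homozygote).
#' @return exact two-sided p-value in (0, 1].
#' @examples
#' hweExactTest(25, 50, 25)   # balanced: p = 1 region
#' hweExactTest(50, 0, 50)    # extreme heterozygote deficit: p << 1e-6
#' @export
hweExactTest <- function(nHomRef, nHet, nHomAlt) {
  counts <- c(nHomRef, nHet, nHomAlt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("at least one genotype required")
  nAlt <- 2 * nHomAlt + nHet          # alternate allele count
  nRef <- 2 * nHomRef + nHet
  rare <- min(nAlt, nRef)             # minor allele count
  if (rare == 0) return(1)
  # support: heterozygote counts with the parity of the rare allele count
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hs))
  # start at the mode-adjacent mid-point and recurse outward;
  # P(h+2)/P(h) = 4 * nA(h) * nB(h) / ((h+2)*(h+1)) with nA/nB the
  # homozygote counts implied by h
  mid <- hs[which.min(abs(hs - rare * (2 * n - rare) / (2 * n)))]
  i0 <- match(mid, hs)
  probs[i0] <- 1
  if (i0 < length(hs)) {
    for (i in (i0 + 1):length(hs)) {
      h <- hs[i - 1]
      a <- (rare - h) / 2             # rare-allele homozygotes at h
      b <- n - h - a                  # common-allele homozygotes at h
      probs[i] <- probs[i - 1] * 4 * a * b / ((h + 2) * (h + 1))
    }
  }
  if (i0 > 1) {
    for (i in (i0 - 1):1) {
      h <- hs[i + 1]
      a <- (rare - h) / 2
      b <- n - h - a
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (a + 1) * (b + 1))
    }
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nHet, hs)]
  if (is.na(pObs)) stop("observed heterozygote count outside support")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Alternate and minor allele frequency from dosages
#'
#' Missing genotypes are excluded (complete-case per variant).
#'
#' @param dosages integer vector in \{0, 1, 2\} or NA.
#' @return named numeric c(af, maf); alternate-allele frequency and
#'   min(af, 1 - af).
#' @examples
#' alleleFrequency(c(0, 1, 2))  # af 0.5
#' @export
alleleFrequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stop("all genotypes missing for this variant")
  if (!all(d %in% c(0, 1, 2))) stop("dosages must be 0, 1 or 2")
  af <- sum(d) / (2 * length(d))
  c(af = af, maf = min(af, 1 - af))
}

#' Variant quality control
#'
#' Applies the four pre-association filters in fixed order, recording the
#' first failure per variant: (1) multiallelic records; (2) exact
#' Hardy-Weinberg test p below \code{hweThreshold}; (3) alternate-allele
#' frequency above \code{afHigh} (near-fixed alternate records); (4) minor
#' allele frequency below \code{mafMin}. Variants with no called genotypes
#' fail with their own status. Missing genotypes are excluded from all
#' counts. The operation is deterministic and idempotent: re-applying it to
#' the passing subset passes every variant again.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param hweThreshold HWE p-value below which a variant fails (default 1e-6).
#' @param afHigh alternate-allele frequency above which a variant fails
#'   (default 0.98).
#' @param mafMin minor allele frequency below which a variant fails
#'   (default 0.01).
#' @return a \linkS4class{QCMask}.
#' @export
applyQC <- function(genotypes, hweThreshold = 1e-6, afHigh = 0.98,
                    mafMin = 0.01) {
  d <- dosages(genotypes)
  nv <- nrow(d)
  status <- rep("pass", nv)
  hwe <- af <- maf <- rep(NA_real_, nv)
  multi <- isMultiallelic(genotypes)
  for (j in seq_len(nv)) {
    dj <- d[j, ]
    dj <- dj[!is.na(dj)]
    if (!length(dj)) { status[j] <- "fail_all_missing"; next }
    fr <- alleleFrequency(dj)
    af[j] <- fr[["af"]]; maf[j] <- fr[["maf"]]
    if (multi[j]) { status[j] <- "fail_multiallelic"; next }
    hwe[j] <- hweExactTest(sum(dj == 0), sum(dj == 1), sum(dj == 2))
    if (hwe[j] < hweThreshold) { status[j] <- "fail_hwe"; next }
    if (af[j] > afHigh) { status[j] <- "fail_af_high"; next }
    if (maf[j] < mafMin) status[j] <- "fail_maf"
  }
  methods::new("QCMask",
    status = factor(status, levels = .qcLevels),
    hweP = hwe, af = af, maf = maf,
    variantKey = variantKeys(genotypes),
    thresholds = c(hwe = hweThreshold, af_high = afHigh, maf_min = mafMin))
}

#' Write / read a QC mask as TSV
#'
#' @param mask a \linkS4class{QCMask}.
#' @param path output file.
#' @return \code{writeQCMask} returns the path invisibly; \code{readQCMask}
#'   a data.frame.
#' @export
writeQCMask <- function(mask, path) {
  df <- data.frame(key = mask@variantKey,
                   status = as.character(mask@status),
                   hwe_p = sprintf("%.12e", mask@hweP),
                   af = mask@af, maf = mask@maf)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeQCMask
#' @export
readQCMask <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$hwe_p <- as.numeric(df$hwe_p)
  df
}
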