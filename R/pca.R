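#' Genotype principal component analysis
#'
#' PCA of QC-passing variants for use as population-stratification
#' covariates. Each variant column is centered by twice its alternate
#' allele frequency and scaled by sqrt(2 p (1 - p)) — the standard
#' frequency scaling for GWAS PCA — with missing dosages mean-imputed
#' (zero after centering) before the decomposition. Sample scores come
#' from the singular value decomposition of the scaled matrix; the sign of
#' each component is fixed so that its largest-magnitude variant loading
#' is positive, making results deterministic.
#'
#' @param genotypes a \linkS4class{GenotypeMatrix}.
#' @param mask optional \linkS4class{QCMask}; only passing variants enter
#'   the PCA. Without a mask all variants are used.
#' @param k number of components (default 10, the number used as GWAS
#'   covariates). Truncated with a warning if it exceeds the rank.
#' @return a \linkS4class{PCResult}.
#' @export
genotypePCA <- function(genotypes, mask = NULL, k = 10) {
  d <- dosages(genotypes)
  if (!is.null(mask)) {
    stopifnot(length(mask@status) == nrow(d))
    d <- d[qcPass(mask), , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no passing variants for PCA")
  n <- ncol(d)
  if (n < k + 1) stop("need at least k + 1 samples")
  X <- t(d)                                 # samples x variants
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1 & !is.na(p)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(X, 2, 2 * p)
  X[is.na(X)] <- 0                          # mean imputation post-centering
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  sv <- svd(X, nu = min(n, ncol(X)), nv = min(n, ncol(X)))
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank) {
    warning("k = ", k, " exceeds rank ", rank, "; truncated")
    k <- rank
  }
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, 0)
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE], 2,
                  sv$d[seq_len(k)] * flip, "*")
  dimnames(scores) <- list(colnames(d), paste0("PC", seq_len(k)))
  ve <- sv$d^2 / sum(sv$d^2)
  methods::new("PCResult", scores = scores,
               varExplained = ve[seq_len(min(length(ve), max(k, 10)))],
               k = as.integer(k), nVariantsUsed = ncol(X))
}

#' Write / read principal component scores as TSV
#'
#' @param pcs a \linkS4class{PCResult}.
#' @param path output file.
#' @export
writePCScores <- function(pcs, path) {
  df <- data.frame(sample_id = rownames(pcs@scores), pcs@scores,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePCScores
#' @export
readPCScores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
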