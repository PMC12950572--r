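#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the cohort generator. Demographic
#' defaults emulate the study population the pipeline targets: about 200
#' dementia-free long-living adults, age 91.96 (SD 2.06) years, 83% women,
#' baseline MMSE 25.63 (SD 2.67) truncated to the dementia-free range
#' [25, 30], follow-up interval 2.0 (SD 0.3) years. Genotypes follow a
#' Balding-Nichols model: per-variant ancestral frequencies uniform in
#' \code{mafRange}, optional two-subpopulation divergence with parameter
#' \code{fst}, genotypes binomial(2, freq).
#'
#' @param nSamples cohort size (default 200).
#' @param nVariants variant count (default 5000).
#' @param nSubpops 1 (panmictic) or 2 (structured).
#' @param fst Balding-Nichols divergence parameter (>= 0; ignored when
#'   \code{nSubpops = 1}).
#' @param mafRange range of ancestral alternate-allele frequencies.
#' @param causal data.frame with columns \code{index} (variant index) and
#'   \code{effect} (CR percent per alternate allele).
#' @param covariateEffects named numeric vector: effect of each named
#'   phenotype column on CR (percent per unit, or per flag for binaries).
#' @param subpopOffset CR percent added to subpopulation 2 (confounding
#'   with ancestry; default 0).
#' @param noiseSd SD of the Gaussian CR noise, in CR percent (default 5,
#'   matching the dispersion of the CR endpoint in cohorts of this kind).
#' @param demographics,prevalence,biomarkers named lists overriding the
#'   defaults documented above (see \code{str(simulationConfig())}).
#' @param fracMultiallelic fraction of variants written as multiallelic
#'   records (exercises the QC filter; default 0.01).
#' @param fracMissing fraction of genotype calls set missing (default 0).
#' @param seed integer RNG seed.
#' @return a validated list with class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nSamples = 200L, nVariants = 5000L,
                             nSubpops = 1L, fst = 0,
                             mafRange = c(0.01, 0.5),
                             causal = data.frame(index = integer(),
                                                 effect = numeric()),
                             covariateEffects = c(),
                             subpopOffset = 0, noiseSd = 5,
                             demographics = list(), prevalence = list(),
                             biomarkers = list(), fracMultiallelic = 0.01,
                             fracMissing = 0, seed = 1L) {
  dem <- utils::modifyList(list(
    ageMean = 91.96, ageSd = 2.06, fracFemale = 0.83,
    mmseMean = 25.63, mmseSd = 2.67,
    intervalMean = 2.0, intervalSd = 0.3), demographics)
  prev <- utils::modifyList(list(
    depression = 0.30, anemia = 0.20, pet = 0.30, hearing_loss = 0.35,
    mobility_limited = 0.25, walking = 0.60, hobby = 0.50,
    living_alone = 0.40), prevalence)
  bio <- utils::modifyList(list(
    bmiMean = 23.90, bmiSd = 8.77, cholMean = 4.92, cholSd = 1.30,
    glucoseMean = 5.42, glucoseSd = 1.54, ldlMean = 3.0, ldlSd = 1.0,
    qolMean = 6, qolSd = 2), biomarkers)
  cfg <- list(nSamples = as.integer(nSamples),
              nVariants = as.integer(nVariants),
              nSubpops = as.integer(nSubpops), fst = fst,
              mafRange = mafRange, causal = causal,
              covariateEffects = covariateEffects,
              subpopOffset = subpopOffset, noiseSd = noiseSd,
              demographics = dem, prevalence = prev, biomarkers = bio,
              fracMultiallelic = fracMultiallelic,
              fracMissing = fracMissing, seed = as.integer(seed))
  fracs <- c(dem$fracFemale, unlist(prev), fracMultiallelic, fracMissing)
  if (any(fracs < 0) || any(fracs > 1))
    stop("all fractions must lie in [0, 1]")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (!(cfg$nSubpops %in% c(1L, 2L))) stop("nSubpops must be 1 or 2")
  if (fst < 0) stop("fst must be >= 0")
  if (length(mafRange) != 2 || mafRange[1] <= 0 || mafRange[2] > 0.5 ||
      mafRange[1] > mafRange[2])
    stop("mafRange must be an increasing pair within (0, 0.5]")
  if (nrow(causal)) {
    if (!all(c("index", "effect") %in% colnames(causal)))
      stop("causal needs columns index, effect")
    if (any(causal$index < 1) || any(causal$index > cfg$nVariants))
      stop("causal indices must lie in 1..nVariants")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Load a SimulationConfig from YAML
#'
#' Top-level YAML keys mirror the arguments of
#' \code{\link{simulationConfig}}; \code{causal} is a list of
#' \code{\{index, effect\}} maps.
#'
#' @param path YAML file.
#' @return a \code{SimulationConfig}.
#' @export
simulationConfigFromYaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$causal))
    y$causal <- do.call(rbind, lapply(y$causal, as.data.frame))
  if (!is.null(y$covariateEffects))
    y$covariateEffects <- unlist(y$covariateEffects)
  if (!is.null(y$mafRange)) y$mafRange <- as.numeric(y$mafRange)
  do.call(simulationConfig, y)
}

#' Simulate a genotype matrix under a Balding-Nichols model
#'
#' Per variant an ancestral frequency is drawn uniformly from
#' \code{mafRange}; with two subpopulations, subpopulation frequencies are
#' drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral p with
#' divergence F = \code{fst} (F = 0 collapses to panmixia). Genotypes are
#' binomial(2, freq). Subpopulation labels are stored in \code{colData};
#' ancestral and subpopulation frequencies in \code{metadata} for test
#' assertions. Deterministic under the configured seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nSamples; m <- config$nVariants
  pAnc <- stats::runif(m, config$mafRange[1], config$mafRange[2])
  subpop <- if (config$nSubpops == 2)
    sample(rep(1:2, length.out = n)) else rep(1L, n)
  if (config$nSubpops == 2 && config$fst > 0) {
    f <- config$fst
    a <- pAnc * (1 - f) / f
    b <- (1 - pAnc) * (1 - f) / f
    pSub <- cbind(stats::rbeta(m, a, b), stats::rbeta(m, a, b))
    # guard against degenerate Beta draws fixing a variant
    pSub <- pmin(pmax(pSub, 1e-4), 1 - 1e-4)
  } else {
    pSub <- cbind(pAnc, pAnc)
  }
  dos <- matrix(0L, m, n)
  for (i in seq_len(n))
    dos[, i] <- stats::rbinom(m, 2, pSub[, subpop[i]])
  if (config$fracMissing > 0) {
    nm <- round(config$fracMissing * length(dos))
    dos[sample(length(dos), nm)] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  altOf <- function(r) sample(setdiff(bases, r), 1)
  alt1 <- vapply(ref, altOf, "")
  multi <- rep(FALSE, m)
  if (config$fracMultiallelic > 0)
    multi[sample(m, round(config$fracMultiallelic * m))] <- TRUE
  alt <- lapply(seq_len(m), function(j) {
    if (multi[j]) {
      rest <- setdiff(bases, c(ref[j], alt1[j]))
      c(alt1[j], sample(rest, 1))
    } else alt1[j]
  })
  chrom <- paste0("chr", sort(sample(1:22, m, replace = TRUE)))
  pos <- stats::ave(seq_len(m), chrom,
                    FUN = function(ix) sort(sample(1e6, length(ix))))
  gm <- GenotypeMatrix(dos, chrom = chrom, pos = as.integer(pos),
                       ref = ref, alt = alt,
                       sampleIds = sprintf("S%04d", seq_len(n)),
                       colData = S4Vectors::DataFrame(subpop = subpop))
  S4Vectors::metadata(gm) <- list(config = config, ancestralFreq = pAnc,
                                  subpopFreq = pSub)
  gm
}

#' Simulate phenotypes on top of a genotype matrix
#'
#' Latent cognitive resilience is generated by the additive model the
#' downstream association analysis assumes: CR = 100 + planted causal
#' dosage effects + named covariate effects + subpopulation offset +
#' Gaussian noise. The follow-up MMSE is then back-computed as
#' round(baseline * CR / 100) clipped to [0, 30], so the CR statistic is
#' the exact generative inverse up to MMSE rounding. Binary covariates are
#' drawn with the configured prevalences; the GDS-5 score is drawn
#' consistently with the depression flag. Deterministic under the
#' configured seed.
#'
#' @param genotypes result of \code{\link{simulateGenotypes}}.
#' @param config the same \code{\link{simulationConfig}}.
#' @return a phenotype data.frame (one row per sample) annotated with
#'   \code{cr}, stages and progression; the latent (pre-rounding) CR is
#'   attached as attribute \code{"crLatent"}.
#' @export
simulatePhenotypes <- function(genotypes, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  n <- ncol(genotypes)
  dem <- config$demographics; prev <- config$prevalence
  bio <- config$biomarkers
  ph <- data.frame(
    sample_id = sampleIds(genotypes),
    age = round(pmax(stats::rnorm(n, dem$ageMean, dem$ageSd), 88), 1),
    sex = stats::rbinom(n, 1, 1 - dem$fracFemale),
    education = sample(0:2, n, replace = TRUE, prob = c(0.35, 0.40, 0.25)))
  ph$mmse_baseline <- pmin(pmax(
    round(stats::rnorm(n, dem$mmseMean, dem$mmseSd)), 25L), 30L)
  ph$interval <- round(pmax(
    stats::rnorm(n, dem$intervalMean, dem$intervalSd), 0.5), 2)
  for (flag in names(prev))
    ph[[flag]] <- stats::rbinom(n, 1, prev[[flag]])
  # GDS-5 consistent with the drawn depression flag (>= 2 iff depressed)
  ph$gds5 <- ifelse(ph$depression == 1,
                    sample(2:5, n, replace = TRUE, prob = c(4, 3, 2, 1)),
                    sample(0:1, n, replace = TRUE))
  ph$depression <- NULL                 # re-derived from gds5 downstream
  ph$bmi <- round(pmax(stats::rnorm(n, bio$bmiMean, bio$bmiSd), 13), 1)
  ph$cholesterol <- round(pmax(stats::rnorm(n, bio$cholMean, bio$cholSd),
                               1.5), 2)
  ph$glucose <- round(pmax(stats::rnorm(n, bio$glucoseMean, bio$glucoseSd),
                           2.0), 2)
  ph$ldl <- round(pmax(stats::rnorm(n, bio$ldlMean, bio$ldlSd), 0.5), 2)
  ph$quality_of_life <- pmin(pmax(
    round(stats::rnorm(n, bio$qolMean, bio$qolSd)), 0L), 10L)

  crLatent <- rep(100, n)
  if (nrow(config$causal)) {
    d <- dosages(genotypes)
    for (r in seq_len(nrow(config$causal))) {
      g <- d[config$causal$index[r], ]
      g[is.na(g)] <- 0
      crLatent <- crLatent + config$causal$effect[r] * g
    }
  }
  ce <- config$covariateEffects
  for (nm in names(ce)) {
    if (nm == "depression") {
      crLatent <- crLatent + ce[[nm]] * as.integer(ph$gds5 >= 2)
    } else {
      if (is.null(ph[[nm]]))
        stop("covariateEffects names unknown column: ", nm)
      crLatent <- crLatent + ce[[nm]] * ph[[nm]]
    }
  }
  subpop <- SummarizedExperiment::colData(genotypes)$subpop
  if (!is.null(subpop) && config$subpopOffset != 0)
    crLatent <- crLatent + config$subpopOffset * (subpop == 2)
  crLatent <- crLatent + stats::rnorm(n, 0, config$noiseSd)

  fu <- round(ph$mmse_baseline * crLatent / 100)
  nClip <- sum(fu < 0 | fu > 30)
  if (nClip > 0)
    message(nClip, " follow-up MMSE value(s) clipped to [0, 30]")
  ph$mmse_followup <- as.integer(pmin(pmax(fu, 0L), 30L))
  ph <- annotateCognition(ph)
  attr(ph, "crLatent") <- crLatent
  ph
}

#' Generate a full synthetic cohort on disk
#'
#' Writes \code{genotypes.vcf.gz}, \code{phenotypes.tsv} and
#' \code{truth.tsv} (the planted causal variants with their keys and
#' effects) into \code{outDir}. Regeneration with the same config is
#' byte-identical.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param outDir writable directory (created if absent).
#' @return named character vector of the three file paths, invisibly.
#' @export
generateCohort <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  gm <- simulateGenotypes(config)
  ph <- simulatePhenotypes(gm, config)
  vcf <- file.path(outDir, "genotypes.vcf.gz")
  tsv <- file.path(outDir, "phenotypes.tsv")
  truth <- file.path(outDir, "truth.tsv")
  writeGenotypeVcf(gm, vcf)
  writePhenotypes(ph, tsv)
  tr <- if (nrow(config$causal)) {
    data.frame(key = variantKeys(gm)[config$causal$index],
               index = config$causal$index, effect = config$causal$effect)
  } else {
    data.frame(key = character(), index = integer(), effect = numeric())
  }
  utils::write.table(tr, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf, phenotypes = tsv, truth = truth))
}
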