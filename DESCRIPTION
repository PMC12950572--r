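Package: cogres
Title: Cognitive Resilience GWAS and Clinical Modelling in Long-Living Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cognitive resilience (CR) in dementia-free
    long-living adults. CR is the ratio of follow-up to baseline Mini-Mental
    State Examination (MMSE) scores expressed as a percentage. The package
    provides MMSE staging and the CR statistic, variant quality control with
    an exact Hardy-Weinberg equilibrium test, genotype principal component
    analysis for population stratification control, a cross-validated
    genome-wide association study using repeated 80% sub-cohorts with
    geometric-mean p-value aggregation, backward-elimination linear and
    logistic models of cognitive decline and MCI-to-dementia progression, and
    a polygenic model of CR fitted by principal-component-projected ridge
    regression. A synthetic cohort generator with optional two-subpopulation
    structure and planted causal variants makes every stage testable without
    access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
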