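---
title: "Modelling cognitive resilience: methods and design notes"
author: "cogres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive resilience: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogres)
```

# The endpoint and its assumptions

Cognitive resilience (CR) is defined from two Mini-Mental State Examination
(MMSE) assessments as `CR = 100 * followup / baseline`, in percent. The
statistic assumes a cohort free of dementia at entry (baseline MMSE >= 25,
enforced by `computeCR()`), so the denominator lies in [25, 30] and CR is
bounded roughly by [0, 120]. Values above 100 are real and common —
test-retest improvement is allowed, not truncated.

MMSE staging follows the three-band rule used throughout: scores above 27
are normal cognition, 25-27 mild cognitive impairment (MCI), below 25
dementia. `classifyMmse()` checks exhaustively that the three bands
partition the integer range with no gaps. Depression is flagged at a
five-item Geriatric Depression Scale score of 2 or more.

**Interval adjustment.** The follow-up interval (years) could enter CR in
two ways: as a divisor (annualized decline) or as a model covariate. The
package treats the raw ratio as the endpoint and puts the interval into
every downstream model as a covariate; this matches the presence of a
follow-up-period row in the progression model's coefficient table, which
is only coherent if the endpoint itself is not already annualized. An
annualized variant, `100 + (CR - 100) / interval`, remains available via
`computeCR(..., annualize = TRUE)` for sensitivity analyses.

# Variant quality control

`applyQC()` applies four filters in a fixed order, recording the first
failure: multiallelic records; exact Hardy-Weinberg equilibrium (HWE)
p below 1e-6; alternate-allele frequency above 0.98 (near-fixed alternate
records, distinct from the MAF filter); minor allele frequency below 0.01.
Missing genotypes are excluded from all counts (complete-case per
variant).

The HWE test is the exact conditional test: given the observed allele
totals, the heterozygote count follows the classical combinatorial null,
and the p-value sums the probabilities of all heterozygote counts no more
probable than the observed one. The exact test (rather than the chi-square
approximation) is the appropriate choice at a cohort of ~200 samples,
where rare-allele genotype counts are small; no mid-p correction is
applied. Numerically the null probabilities are built by the stable
mid-point recurrence and normalized, which avoids factorial overflow; the
test suite checks equality against a direct log-factorial enumeration at
1e-12 on hundreds of random configurations up to n = 200.

# Population structure

`genotypePCA()` computes sample principal components from QC-passing
variants with the standard GWAS frequency scaling: each variant column is
centered at twice its allele frequency and scaled by `sqrt(2p(1-p))`;
missing dosages are mean-imputed after centering. Components are made
deterministic by fixing each column's sign so that its largest-magnitude
variant loading is positive. The first 10 PCs are the default
stratification covariates, matching the association model below.

# Cross-validated GWAS

Each variant is tested by OLS of CR on allele dosage (0/1/2 coding of the
alternate allele) with covariates age, sex, education (ordinal 0/1/2),
the first 10 PCs, and (by default, toggleable) the follow-up interval.
The p-value is the two-sided t-test of the dosage coefficient.

Rather than one GWAS, the pipeline runs `folds = 5` independent random
sub-cohorts, each containing `frac = 0.8` of the samples drawn without
replacement. The folds deliberately overlap — they are repeated random
subsamples, not a disjoint partition: the stated goal is stability of the
hits under cohort perturbation, not out-of-sample error. Fold results are
averaged: arithmetic mean for coefficients, geometric mean for p-values,
the latter computed in log space so that p-values near the double minimum
do not underflow. Variants untestable in a fold (e.g. monomorphic in the
subsample) are averaged over the available folds with the fold count
reported. Significance tiers use strict inequalities on the averaged p:
genome-wide below 5e-8, suggestive below 5e-7.

**Calibration of the aggregated p-values.** The geometric mean of
correlated uniform p-values is not itself uniform: its null median falls
below 0.5, so a genomic-control lambda computed on the averaged values
overstates inflation even in a perfectly homogeneous cohort, while its
extreme tail is *conservative* (a variant must be small in most folds to
stay small after averaging). For this reason `manhattanQQ()` reports as
its headline inflation factor the median of the per-fold lambdas — each
fold is a calibrated GWAS and this is the standard stratification
diagnostic — alongside the lambda of the averaged values that the QQ plot
displays. The acceptance suite checks both effects: on panmictic null
cohorts (three seeds, 200 samples, 2000 variants each) the per-fold
lambda must sit in [0.9, 1.1] and the tail rejection rate of the averaged
p at 1e-3 must not exceed three times nominal; under a confounded
two-subpopulation cohort (F_ST 0.05 with an ancestry-correlated CR offset
of 10 percent, i.e. two noise SDs) rejections must be grossly inflated
without PC covariates and return to within twice nominal with 10 PCs.

# Clinical models

The modelling chain mirrors common epidemiological practice. Screening:
each candidate is fitted alone with the protected covariates (age, sex,
baseline MMSE, interval for the linear CR models; age, sex, interval for
the logistic progression models — baseline MMSE is excluded there, since
the progression analysis is already restricted to the MCI stratum).
Multivariable: backward elimination starting from all candidates, dropping
one term per iteration — the largest p at or above alpha = 0.05, ties
broken by term name order — using partial F-tests for the linear model and
likelihood-ratio tests for the logistic one. Protected covariates are
never dropped, and the code asserts this on every run. Complete-case
handling is used throughout. Odds ratios are Wald: exp(beta +/- z se)
with z = qnorm(0.975) = 1.959964; the test suite reproduces three
published (log-odds, SE) -> OR (CI) rows exactly at their printed
2-decimal precision, which validates this convention.

Quasi-perfect separation in logistic fits is detected (via the fitted
0/1 probability warning or an extreme coefficient) and flagged
`unstable` rather than silently reported.

# Polygenic model

The design matrix holds the dosages of every variant below the suggestive
threshold (5e-7) plus thirteen clinical columns: baseline MMSE, GDS-5
(entered as the raw 0-5 score, since it is listed alongside continuous
predictors), pet ownership, hearing loss, limited mobility, walking,
quality of life (0-10), BMI, anemia, total cholesterol, glucose, and the
age and sex adjustment. Five continuous features are standardized with
fixed training constants — age (91.96, 2.06), MMSE (25.63, 2.67), BMI
(23.90, 8.77), glucose (5.42, 1.54), cholesterol (4.92, 1.30) — and the
outcome with mean 96.96 and SD 10.04; binary and ordinal features pass
through unstandardized.

The standardized design is column-centered, projected onto its first k
principal components, and fitted by ridge regression minimizing
`sum((y - yhat)^2) + lambda * sum(beta^2)` with an unpenalized intercept.
Working in the principal basis makes the solution closed-form and
diagonal, so the exhaustive hyperparameter grid — integer k from 5 to 55
(truncated at the design rank) crossed with 13 log-spaced lambdas from
1e-3 to 1e3 — costs one SVD. Selection is by highest held-out R-squared
on a seeded 80/20 split (the selection criterion and split proportions
are package choices; only the grid ranges are prescribed), with ties
resolved toward fewer projections and smaller lambda. The winning model
is refit on the training split and reported with both R-squared values.

Coefficients are reverse-transformed through the projection and both
standardizations into `CR = intercept + sum(coef_j * raw_feature_j)`;
the identity between the projected-space and raw-scale prediction routes
is asserted at 1e-10, and the closed form is checked against a
gradient-descent minimizer of the stated loss.

# The synthetic cohort generator

The generator exists so that every stage has a ground truth. Genotypes
follow a Balding-Nichols model: ancestral frequencies uniform on
`mafRange` (default 0.01-0.5), optional two-subpopulation divergence with
parameter F_ST via Beta-distributed subpopulation frequencies, genotypes
binomial(2, freq). Phenotypes are generated by exactly the additive model
the GWAS assumes: latent CR = 100 + planted dosage effects + named
covariate effects + subpopulation offset + Gaussian noise, after which
the follow-up MMSE is back-computed as `round(baseline * CR / 100)`
clipped to [0, 30] — so the CR statistic is the exact generative inverse
up to MMSE rounding.

Default demographics emulate the target population: 200 samples, age
91.96 (SD 2.06), 83% female, baseline MMSE 25.63 (SD 2.67) truncated to
the dementia-free range, interval 2.0 (SD 0.3) years. Where no published
value exists, defaults were fixed once at values a geriatric-cohort
analyst would call realistic and are all overridable: CR noise SD 5
percent (consistent with a CR interquartile range of roughly 94-101),
flag prevalences (depression 0.30, anemia 0.20, pet 0.30, hearing loss
0.35, limited mobility 0.25, walking 0.60, hobby 0.50, living alone
0.40), and conventional biomarker spreads.

Two honest caveats about what passing tests show. First, the truncation
of baseline MMSE to [25, 30] (the dementia-exclusion rule) shifts its
realized mean above the configured 25.63; the moment-recovery test
therefore checks age, sex and interval against the configuration and
checks MMSE on its support. Second, the generator draws variants
independently — no linkage disequilibrium, no relatedness, no genotyping
batch structure — and covariates independently of genotype except through
the explicit subpopulation offset. Calibration and power results on these
cohorts demonstrate correctness of the machinery, not performance on real
genomes, where LD and cryptic relatedness would demand additional care
(e.g. LD pruning before PCA, mixed models for kinship), both explicitly
out of scope.

# Numerical choices and degenerate inputs

- HWE: mid-point recurrence with normalization; monomorphic variants have
  a single attainable configuration and return p = 1; the observed
  probability is compared with a 1 + 1e-12 relative tolerance, the usual
  guard against ties lost to floating-point rounding.
- GWAS: per fold, variants without missing calls are residualized against
  the covariates in one QR decomposition (Frisch-Waugh), which matches
  the per-variant `lm.fit` route at 1e-10 and keeps a 2000-variant,
  5-fold analysis near-instant; fold p-values are floored at 1e-300
  before log-averaging.
- PCA: components below a 1e-10 relative singular-value threshold are
  treated as null; requesting more truncates with a warning.
- Ridge: k above the design rank is a `singular projection` error in a
  direct fit, and a truncation with warning in the grid search.
- Backward elimination is deterministic: largest p first, ties broken
  lexicographically; re-running on identical input reproduces the same
  retained set and drop order.
- Problem sizes in the test and acceptance suites (200-500 samples,
  200-5000 variants, 3-20 replicates) were chosen as the smallest cohorts
  at which the checked properties are statistically unambiguous.

# Known limitations

- The MMSE is an integer screen; CR inherits a granularity of roughly
  3-4 percent per point, which the generator reproduces via rounding.
- The aggregated (geometric-mean) p-value is a stability statistic, not a
  calibrated tail probability; its thresholds (5e-8, 5e-7) should be read
  as operational cutoffs, and the per-fold lambda is the appropriate
  stratification diagnostic.
- Fold draws are independent, so two sub-cohorts can coincide by chance
  in tiny cohorts; with 200 samples this has negligible probability.
- The polygenic model's held-out R-squared comes from a single seeded
  split; repeated-split or cross-validated evaluation is deliberately not
  implemented.
- No gene or regulatory annotation of hits, no mixed-model kinship
  correction, and no sample-level QC are provided.
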