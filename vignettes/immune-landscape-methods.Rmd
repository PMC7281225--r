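---
title: "Methods: immune scoring, enrichment and survival in immunocyt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune scoring, enrichment and survival in immunocyt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(immunocyt)
```

This vignette documents the statistical machinery of `immunocyt`: the score
definitions and their conventions, the group-comparison and survival
procedures, the enrichment engine, the synthetic cohort generator, and the
numerical and design decisions taken where the underlying conventions were
genuinely open.

## Score definitions and conventions

**CYT.** The cytolytic activity score of a sample is the geometric mean of
GZMA and PRF1 in TPM, `exp(mean(ln(TPM + c)))`. Whether published uses of
this score employed a pseudocount is typically unstated; we default to
`c = 0.01`, which prevents `ln 0` while perturbing typical TPM values
(tens) by well under one percent. With `c = 0` the score of any sample with
a zero count is exactly 0, which is also the mathematically correct limit.
The pseudocount is configurable and recorded in the score-frame header.

**Log-average panel scores.** The APOBEC3 score and the checkpoint index
are "log average expression" aggregates. The literature phrase pins down
neither base nor offset, so the package fixes one convention —
`mean(log2(TPM + 1))` over the panel — and writes base and pseudocount into
every output header for provenance. The checkpoint index composition is
likewise not standardized; we use the full eleven-marker exhaustion panel
(PDCD1, CD274, CTLA4, IDO1, IDO2, LAG3, HAVCR2, PDCD1LG2, TIGIT, ADORA2A,
VSIR) as the default index, and expose the four-marker core subset
(PDCD1, CTLA4, CD274, LAG3) as the panel used for two-factor survival
stratification. Marker aliases common in the literature (PD-1, PD-L1,
PD-L2, TIM3, VISTA) are resolved through one explicit alias table, never by
fuzzy matching.

**Median dichotomization.** "High" means strictly greater than the cohort
median; ties go to "low". With an odd tie-free cohort this puts the extra
sample in the low group — the only rule consistent with a 186-low/185-high
split of 371 samples. All values equal therefore yields zero "high"
samples, which is intended behavior, not an error.

**SCNA events.** A segment qualifies when its log2 segment mean is
`>= 0.6` or `<= -0.4`, boundaries inclusive. The phrase "sum of the segment
mean changes" is ambiguous between counting qualifying segments and summing
their magnitudes; event counts are the unit used when plotting SCNA burden,
so counting is the default and magnitude summing is available behind
`mode = "magnitude"`. SEG coordinates are kept 1-based and inclusive (the
TCGA convention); no interval arithmetic is ever performed on them, only
thresholding of means, so no half-open conversion is needed.

**Repertoire metrics.** Richness is the unique clonotype count; CPK is
`1000 * unique CDR3 / total TCR reads`, bounded by construction in
[0, 1000]. Zero total reads makes diversity undefined and raises a typed
error rather than returning 0 — a 0 would be indistinguishable from a
monoclonal repertoire.

## Group comparisons

Continuous features use the Mann-Whitney test with
`U = #\{x_i > y_j\} + ties/2`. For combined `n <= 12` the two-sided p-value
is computed by full enumeration of all `choose(n, n_x)` group assignments
of the pooled values, which stays exact under ties. Larger samples use the
normal approximation with tie-corrected variance and a 0.5 continuity
correction. The approximation is accurate to well under 0.05 against the
enumeration on tie-free fixtures with at least 3 per group; with heavy ties
or 2 per group the exact distribution is too coarse for any Gaussian to
track, which is why `auto` mode switches to enumeration exactly where that
matters. Categorical features use the Pearson chi-square statistic without
continuity correction on the full r x c table. Raw two-sided p-values are
reported; Benjamini-Hochberg q-values are an optional extra column, never a
replacement.

## Survival analysis

Kaplan-Meier estimation, the log-rank test and Cox partial-likelihood
maximization are standard machinery and are delegated to the `survival`
package behind the module interface (`km_fit`, `log_rank`, `cox_fit`);
the tests verify the wrappers against hand product-limit computations, the
textbook Greenwood formula, and an independently coded partial-likelihood
score function evaluated at the returned coefficients.

Conventions: Efron tie handling by default (month-resolution times tie
heavily; Breslow is available behind a flag and coincides with Efron on
tie-free data); Wald confidence intervals `exp(beta ± 1.96 se)`; median
survival as the first time the curve reaches 0.5, with its 95% CI from the
log-log transformed band. A median or bound never reached is reported as
`NA` and printed as "NR" — a sentinel, never infinity-as-number.

The univariate-to-multivariate workflow fits each candidate covariate
alone and selects a candidate when **any** of its coefficient-level Wald
p-values is below `alpha = 0.05`; a multi-level factor enters or leaves as
a block. This any-level rule is deliberate: it is the only simple rule that
keeps a stage factor in the joint model when only its higher stages are
significant, which is the pattern reported for cohorts of this kind.
Reference levels follow the conventional baselines: stage I, etiology
"none", TIL negative, score group "low". Samples with a missing endpoint or
covariate are dropped per analysis, never imputed and never dropped
globally.

Two-factor stratification crosses the score groups with a median split of
an exhaustion marker, runs a k-group log-rank test (empty cells are dropped
with a warning and the degrees of freedom reduced), and ranks the strata by
restricted mean survival time. The RMST horizon is the smallest per-group
maximum follow-up, so no group's curve is extrapolated.

## The enrichment engine

Genes are ranked by signal-to-noise
`(mean_high - mean_low) / (sd_high + sd_low)` on `log2(TPM + 1)`, each
group sd floored at `max(0.2, 0.2 |mean|)`; ties in the metric are broken
lexicographically so rankings are reproducible. The running sum increments
by `|metric|^w / sum_hits |metric|^w` at set members and decrements by
`1/(N - N_hits)` elsewhere; the enrichment score is the signed extremum of
the walk, which ends at zero by construction (asserted to 1e-12 in tests).
The default weight is 1 (the classic weighted statistic); weight 0 is kept
because it makes fixtures hand-checkable. If every hit metric is exactly
zero under a positive weight, hits are weighted uniformly rather than
dividing by zero.

NES divides the observed ES by the mean |null ES| of matching sign;
the nominal p is the same-sign tail fraction with an add-one correction.
When a permutation null contains no same-sign values, NES and FDR are
reported as `NA` rather than silently substituting the opposite tail.
Permutations default to phenotype label shuffling when both groups have at
least 7 samples and to random equal-size gene sets otherwise, with the mode
recorded in every result; phenotype permutations are shared across sets so
a collection is tested against a common null. FDR uses the ratio-of-tails
estimator over the pooled, per-set-normalized null distributions. Set
members absent from the expression matrix are dropped with a logged count.
Published ES/NES tables from other tools are matched qualitatively (sign
and significance), not numerically, because permutation mode, count and
weighting of such runs are generally unreported.

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. A
single latent immune-heat factor `h ~ N(0,1)` per sample drives:

- `log2(TPM + 1)` of GZMA/PRF1, HLA-A/B and the planted immune-response
  genes (loading 1.0), the APOBEC3 genes (0.8) and the checkpoint markers
  (0.8), each plus `N(0, 1)` noise, back-transformed as `max(2^x - 1, 0)`
  so TPM stays non-negative and zeros are permitted;
- SCNA counts, Poisson with log-rate `log(30) - 0.3 h` (hot tumors carry
  fewer alterations), realized as that many qualifying segments plus three
  neutral ones;
- repertoire richness `300 + 60 h` clonotypes against a fixed 10,000 reads;
- TIL positivity, logistic in `h`;
- event hazards, exponential with log hazard ratio `-0.5` per unit `h`.

A second exhaustion-specific latent `e ~ N(0,1)` loads on the checkpoint
markers (1.2) and adds `+0.8` per unit to the log hazard. This second axis
is a deliberate departure from a pure one-factor design: with a single
factor, any two groups that both load positively on `h` would order their
crossed survival strata by `h` alone, and the clinically observed pattern —
score-high/exhaustion-low best, score-low/exhaustion-high worst — would be
unreachable. Exhaustion acting as an independent harmful axis is exactly
the immunosuppressive-feedback interpretation of checkpoint expression, and
its default magnitudes were fixed once at design time from a small pilot
power analysis of that ordering.

Censoring is an independent exponential tuned so that the expected censored
fraction at `h = 0` equals `censor_rate` (default 0.65, a typical
overall-survival censoring fraction for a hepatocellular carcinoma cohort);
the baseline hazard of 0.01/month puts the baseline median near 70 months.
Endpoint-specific baseline multipliers (OS 1.0, DSS 0.8, PFI 2.0, DFI 1.5)
make progression events earlier than deaths. Endpoints are drawn
independently per endpoint — the generator does not enforce, e.g., that a
DSS event implies an OS event. Clinical covariates other than TIL are drawn
independently of `h`, matching the observation that demographics do not
separate the score groups. Survival draws are transformed from uniforms
drawn in a fixed order, so cohorts with the same seed and different hazard
parameters share all randomness — which is what makes the paired-seed
monotonicity tests exact rather than stochastic.

What the generator does **not** emulate: read-level RNA-seq noise and
library-size artifacts, correlated gene-gene structure beyond the two
latent axes, genome-positioned SCNA hotspots, CDR3 sequence content, and
informative censoring. Passing tests on synthetic cohorts therefore
demonstrate the correctness and power of the statistical machinery under
the stated generative model, not robustness to every artifact of real
cohorts.

## Problem sizes used in validation

The test suite exercises: type-I error of the Mann-Whitney and log-rank
tests on 500 null cohorts of n = 200; Cox hazard-ratio recovery and 95% CI
coverage on 500 two-group exponential cohorts of n = 2000; the survival
direction and four-group ordering on 100 cohorts of n = 400; planted
gene-set detection on 50 cohorts of n = 400 at 1000 permutations; and
uniform calibration of enrichment p-values over 200 random sets. These
sizes give binomial standard errors comfortably inside the asserted bands
while keeping the full suite around a minute of CPU.

## Known limitations

- The checkpoint-index composition and aggregation are a declared package
  convention; scores are comparable within a run, not across tools.
- No z-scoring or cross-cohort normalization is applied; scores are
  cohort-internal.
- No proportional-hazards diagnostics, time-varying covariates or
  competing-risks models are provided.
- Expression input must already be collapsed to unique gene symbols;
  versioned or multi-mapped identifiers are the caller's responsibility.
- The Mann-Whitney normal mode, like any Gaussian approximation, is not
  trustworthy below about 3 observations per group; `auto` mode never uses
  it there.
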