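Package: immunocyt
Title: Cytolytic-Activity Immune Landscape Analysis for Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-sample immune scoring of bulk tumor expression cohorts
    (cytolytic activity from GZMA/PRF1, APOBEC3 score, immune inhibitory
    checkpoint index, HLA-A/B expression, somatic copy-number alteration
    event counts, T-/B-cell receptor repertoire richness and diversity),
    median dichotomization into score-high/low groups, group-comparison
    statistics (Mann-Whitney, chi-square), a gene-set enrichment engine
    (weighted Kolmogorov-Smirnov running sum, permutation-based NES, nominal
    p and FDR q), and survival analysis (Kaplan-Meier, log-rank, Cox
    proportional hazards with univariate-to-multivariate covariate
    selection), plus a synthetic cohort generator with a latent
    immune-activity factor for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
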