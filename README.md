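# immunocyt

Immune-landscape analysis of bulk tumor expression cohorts, built around the
cytolytic activity score (CYT). Hepatocellular carcinomas — and solid tumors
generally — differ widely in how "hot" their immune microenvironment is, and
that difference tracks prognosis and candidacy for checkpoint blockade.
`immunocyt` quantifies that axis per sample, splits a cohort at the score
median, and characterizes what else separates the resulting groups:
mutagenic enzyme expression, checkpoint/exhaustion markers, antigen
presentation, copy-number burden, receptor-repertoire diversity, enriched
gene programs, and survival.

It is intended for computational biologists analyzing TCGA-style cohorts
(a TPM expression matrix, a clinical table with censored endpoints, SEG
copy-number segments, and a repertoire summary), and ships a synthetic
cohort generator with a latent immune-activity factor so the entire chain
can be validated without any external download.

## The scores

For sample *j* with expression in transcripts per million (TPM):

- **CYT** (cytolytic activity): the geometric mean of granzyme A and
  perforin, `exp(mean(ln(TPM_g + c)))` over `g ∈ {GZMA, PRF1}` with
  pseudocount `c = 0.01` by default.
- **APOBEC3 score**: `mean(log2(TPM + 1))` over the seven APOBEC3
  cytidine-deaminase genes (A/B/C/D/F/G/H).
- **Checkpoint (exhaustion) index**: the same log-average over an
  eleven-marker exhaustion panel (PD-1, PD-L1, CTLA4, IDO1, IDO2, LAG3,
  TIM3, PD-L2, TIGIT, ADORA2A, VISTA, as HGNC symbols); a four-marker core
  panel (PD-1, CTLA4, PD-L1, LAG3) is used for two-factor survival
  stratification.
- **SCNA events**: the number of copy-number segments whose log2 segment
  mean is ≥ 0.6 or ≤ −0.4 (boundaries inclusive).
- **TCR/BCR richness** and **CPK**: unique clonotype counts, and clonotypes
  per kilo-reads `1000 · unique CDR3 / total TCR reads`.

Groups are formed by **median dichotomization**: a sample is "high" when
its score strictly exceeds the cohort median (ties go to "low"; 371
tie-free samples split 185 high / 186 low). Group comparisons use the
Mann-Whitney test (full enumeration for combined n ≤ 12, tie-corrected
normal approximation otherwise) and Pearson chi-square without continuity
correction. Gene-set enrichment uses the weighted Kolmogorov-Smirnov
running sum on a signal-to-noise ranking, with permutation-based NES,
nominal p, and ratio-of-tails FDR. Survival analysis provides Kaplan-Meier
estimates with Greenwood errors and log-log median CIs, the log-rank test,
and Cox proportional-hazards models with a univariate screen followed by a
joint multivariate fit.

## Worked example

```r
library(immunocyt)

cohort <- generate_cohort(sim_config(n_samples = 371, seed = 11))
fit <- immune_landscape(cohort$expression, cohort$clinical,
                        segments = cohort$segments,
                        repertoire = cohort$repertoire,
                        gene_sets = planted_gene_set(sim_config()),
                        gsea_n_perm = 1000, seed = 11)
print(fit)
```

```
Immune landscape fit: 371 samples, grouped by cyt (median split)
  cyt-high: 185, cyt-low: 186
Score comparisons (high vs low):
  apobec3            p = 6.68e-32
  checkpoint_index   p = 1.79e-12
  hla_a              p = 6.12e-18
  hla_b              p = 7.82e-17
  scna_events        p = 3.26e-30
  tcr_richness       p = 6.25e-43
  bcr_richness       p = 6.53e-43
  cpk                p = 6.25e-43
OS log-rank p = 5.56e-05
DSS log-rank p = 0.000391
PFI log-rank p = 2.62e-05
DFI log-rank p = 1.51e-06
Multivariate cyt-high HR = 0.482 (95% CI 0.334-0.696), p = 9.72e-05
```

The cohort was generated with a protective immune effect, so every planted
association is recovered: CYT-high tumors show higher APOBEC3 and
checkpoint-marker expression, higher HLA-A/B, fewer SCNA events, richer
repertoires, and a multivariate hazard ratio well below 1 for all four
endpoints. Per-group Kaplan-Meier fits are available under
`fit$survival$OS$fits`:

```
Kaplan-Meier fit: n = 185, events = 50
  median survival 88.5 months, 95% CI (72.5-NR)
```

("NR" marks a median or CI bound never reached within follow-up.)
`summary(fit)` adds demographics, the enrichment table and the two-factor
CYT × exhaustion-marker stratifications; `plot(fit, endpoint = "OS")` draws
the KM curves; `coef(fit)` returns the multivariate log-hazards.

A file-based run of the same analysis:

```r
run_pipeline(pipeline_config(input_dir = "my_cohort/", output_dir = "report/"))
```

writes `scores.tsv`, `demographics.tsv`, `score_tests.tsv`, `gsea.tsv`,
per-group KM tables, Cox tables and a `manifest.json` holding the seed and
config hash that make the run reproducible. A thin command-line wrapper
with `simulate` / `score` / `survival` / `gsea` / `run` subcommands lives
at `inst/scripts/immunocyt.R`.

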