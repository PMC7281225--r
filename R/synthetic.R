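#' Simulation configuration for synthetic tumor cohorts
#'
#' The generator is built around a single latent immune-activity ("heat")
#' factor h ~ N(0, 1) per sample that simultaneously raises cytolytic and
#' immune gene expression, raises checkpoint-marker expression, lowers
#' copy-number alteration burden, raises repertoire diversity and lowers the
#' event hazard. A second exhaustion-specific latent e ~ N(0, 1) loads on
#' the checkpoint markers only and raises the hazard, so that high
#' exhaustion is harmful beyond the shared immune-heat axis.
#'
#' @param n_samples Cohort size (>= 2).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param heat_effect_expr Loading of h on log2 expression of the cytolytic
#'   genes (GZMA, PRF1), HLA-A/B and the planted immune-response genes.
#' @param apobec_effect Loading of h on the seven APOBEC3 genes.
#' @param checkpoint_effect Loading of h on the eleven checkpoint markers.
#' @param exhaustion_loading Loading of the exhaustion latent e on the
#'   checkpoint markers.
#' @param noise_sd Residual sd of log2 expression (> 0).
#' @param n_decoy Number of unloaded decoy genes.
#' @param n_planted Number of planted heat-loaded genes (the "immune
#'   response" set used to exercise the enrichment engine).
#' @param scna_base_rate Poisson mean of SCNA events at h = 0 (> 0).
#' @param scna_heat_slope Log-linear effect of h on the SCNA rate
#'   (negative: hot tumors carry fewer alterations).
#' @param tcr_base Baseline unique CDR3 clonotype count.
#' @param tcr_total_reads Fixed total TCR-region read count per sample.
#' @param bcr_base Baseline BCR clonotype count.
#' @param repertoire_heat_slope Clonotypes gained per unit h.
#' @param hazard_log_hr Log hazard ratio per unit h (negative: protective
#'   immunity).
#' @param exhaustion_hazard_log_hr Log hazard ratio per unit e (positive:
#'   harmful exhaustion).
#' @param baseline_hazard Event hazard per month at h = e = 0 (> 0).
#' @param censor_rate Target censoring fraction in (0, 1); censoring is an
#'   independent exponential tuned to this fraction at h = 0.
#' @param til_logit_slope Logistic slope of TIL positivity on h.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 371L, seed = 1L,
                       heat_effect_expr = 1.0, apobec_effect = 0.8,
                       checkpoint_effect = 0.8, exhaustion_loading = 1.2,
                       noise_sd = 1.0, n_decoy = 200L, n_planted = 30L,
                       scna_base_rate = 30, scna_heat_slope = -0.3,
                       tcr_base = 300L, tcr_total_reads = 10000L,
                       bcr_base = 150L, repertoire_heat_slope = 60,
                       hazard_log_hr = -0.5, exhaustion_hazard_log_hr = 0.8,
                       baseline_hazard = 0.01, censor_rate = 0.65,
                       til_logit_slope = 1.0) {
  cfg <- list(n_samples = as.integer(n_samples), seed = as.integer(seed),
              heat_effect_expr = heat_effect_expr, apobec_effect = apobec_effect,
              checkpoint_effect = checkpoint_effect,
              exhaustion_loading = exhaustion_loading, noise_sd = noise_sd,
              n_decoy = as.integer(n_decoy), n_planted = as.integer(n_planted),
              scna_base_rate = scna_base_rate, scna_heat_slope = scna_heat_slope,
              tcr_base = as.integer(tcr_base),
              tcr_total_reads = as.integer(tcr_total_reads),
              bcr_base = as.integer(bcr_base),
              repertoire_heat_slope = repertoire_heat_slope,
              hazard_log_hr = hazard_log_hr,
              exhaustion_hazard_log_hr = exhaustion_hazard_log_hr,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              til_logit_slope = til_logit_slope)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_samples < 2L) ic_config_error("n_samples must be >= 2, got %d", cfg$n_samples)
  if (!(cfg$noise_sd > 0)) ic_config_error("noise_sd must be > 0")
  if (!(cfg$censor_rate > 0 && cfg$censor_rate < 1))
    ic_config_error("censor_rate must lie in (0, 1), got %g", cfg$censor_rate)
  if (!(cfg$scna_base_rate > 0)) ic_config_error("scna_base_rate must be > 0")
  if (!(cfg$baseline_hazard > 0)) ic_config_error("baseline_hazard must be > 0")
  if (!(cfg$tcr_total_reads > 0)) ic_config_error("tcr_total_reads must be > 0")
  if (cfg$n_decoy < 0L || cfg$n_planted < 0L)
    ic_config_error("gene counts must be non-negative")
  invisible(cfg)
}

#' Null simulation configuration
#'
#' Every effect parameter (expression loadings, SCNA slope, repertoire
#' slope, both hazard terms, TIL slope) set to zero; used for type-I-error
#' and calibration suites.
#'
#' @param n_samples Cohort size.
#' @param seed Integer seed.
#' @return A `sim_config` with all effects zero.
#' @export
null_config <- function(n_samples = 371L, seed = 1L) {
  sim_config(n_samples = n_samples, seed = seed,
             heat_effect_expr = 0, apobec_effect = 0, checkpoint_effect = 0,
             exhaustion_loading = 0, scna_heat_slope = 0,
             repertoire_heat_slope = 0, hazard_log_hr = 0,
             exhaustion_hazard_log_hr = 0, til_logit_slope = 0)
}

# Endpoint-specific baseline hazard multipliers: progression and recurrence
# occur earlier than death, disease-specific death later than all-cause.
endpoint_multipliers <- c(OS = 1.0, DSS = 0.8, PFI = 2.0, DFI = 1.5)

#' Generate a synthetic tumor cohort
#'
#' Produces the four linked inputs of the analysis (expression matrix,
#' clinical table, segment profiles, repertoire summary) with the planted
#' statistical structure described in [sim_config()], deterministically for
#' a given configuration. log2(TPM + 1) of each gene is baseline +
#' loading * latent + N(0, noise_sd), back-transformed as
#' `max(2^x - 1, 0)`. Per-sample SCNA events are Poisson with log-rate
#' `log(scna_base_rate) + scna_heat_slope * h`, realized as that many
#' qualifying segments (|seg mean| beyond the calling thresholds) plus three
#' neutral segments. Survival times are exponential with hazard
#' `baseline_hazard * mult_endpoint * exp(hazard_log_hr * h +
#' exhaustion_hazard_log_hr * e)` under independent exponential censoring
#' tuned to `censor_rate`.
#'
#' @param config A `sim_config`.
#' @return List with `expression` (matrix), `clinical` (data frame),
#'   `segments` (named list), `repertoire` (data frame) and `latent`
#'   (data frame with the per-sample factors h and e, for validation).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, as.list(config))
  validate_sim_config(config)
  n <- config$n_samples
  set.seed(config$seed)
  samples <- sprintf("S%04d", seq_len(n))

  h <- stats::rnorm(n)
  e <- stats::rnorm(n)

  ## --- expression -----------------------------------------------------
  planted <- if (config$n_planted > 0L) sprintf("PLANT%03d", seq_len(config$n_planted)) else character(0)
  decoys <- if (config$n_decoy > 0L) sprintf("DECOY%03d", seq_len(config$n_decoy)) else character(0)
  genes <- c("GZMA", "PRF1", apobec3_panel(), checkpoint_panel(),
             "HLA-A", "HLA-B", planted, decoys)
  baseline <- c(4, 4, rep(3, 7), rep(2, 11), 8, 8, rep(3, length(planted)),
                stats::runif(length(decoys), 1, 7))
  loading_h <- c(rep(config$heat_effect_expr, 2), rep(config$apobec_effect, 7),
                 rep(config$checkpoint_effect, 11),
                 rep(config$heat_effect_expr, 2),
                 rep(config$heat_effect_expr, length(planted)),
                 rep(0, length(decoys)))
  loading_e <- ifelse(genes %in% checkpoint_panel(), config$exhaustion_loading, 0)
  x <- baseline + outer(loading_h, h) + outer(loading_e, e) +
    matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
           nrow = length(genes))
  expr <- pmax(2^x - 1, 0)
  dimnames(expr) <- list(genes, samples)

  ## --- copy-number segments -------------------------------------------
  lambda <- exp(log(config$scna_base_rate) + config$scna_heat_slope * h)
  k <- stats::rpois(n, lambda)
  n_seg <- k + 3L                      # k qualifying events + 3 neutral segments
  tot <- sum(n_seg)
  owner <- rep.int(seq_len(n), n_seg)
  # within each sample the first k rows are events, the last 3 neutral
  is_event <- sequence(n_seg) <= rep.int(k, n_seg)
  mean_ev <- ifelse(stats::runif(tot) < 0.5,
                    stats::runif(tot, 0.6, 2.0), stats::runif(tot, -2.0, -0.4))
  mean_nt <- stats::runif(tot, -0.35, 0.55)
  start <- sample.int(1e8, tot, replace = TRUE)
  all_seg <- data.frame(
    chrom = as.character(sample(1:22, tot, replace = TRUE)),
    start = start,
    end = start + sample.int(5e6, tot, replace = TRUE),
    num_markers = sample.int(500L, tot, replace = TRUE) + 4L,
    seg_mean = round(ifelse(is_event, mean_ev, mean_nt), 4),
    stringsAsFactors = FALSE)
  segments <- split(all_seg, factor(owner, levels = seq_len(n)))
  segments <- lapply(segments, function(d) { rownames(d) <- NULL; d })
  names(segments) <- samples

  ## --- repertoire ------------------------------------------------------
  tcr <- pmin(pmax(0L, as.integer(round(config$tcr_base + config$repertoire_heat_slope * h))),
              config$tcr_total_reads)
  bcr <- pmax(0L, as.integer(round(config$bcr_base + 0.5 * config$repertoire_heat_slope * h)))
  repertoire <- data.frame(sample_id = samples, tcr_unique_cdr3 = tcr,
                           tcr_total_reads = config$tcr_total_reads,
                           bcr_unique_clonotypes = bcr, stringsAsFactors = FALSE)

  ## --- clinical covariates ---------------------------------------------
  age <- round(pmin(pmax(stats::rnorm(n, 59.5, 13.5), 18), 90), 1)
  sex <- factor(ifelse(stats::runif(n) < 0.67, "male", "female"),
                levels = clinical_levels$sex)
  stage <- factor(sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                         prob = c(0.47, 0.24, 0.26, 0.03)),
                  levels = clinical_levels$stage)
  stage[stats::runif(n) < 0.08] <- NA
  inflammation <- factor(sample(c("none", "mild", "severe"), n, replace = TRUE,
                                prob = c(0.5, 0.42, 0.08)),
                         levels = clinical_levels$inflammation)
  inflammation[stats::runif(n) < 0.3] <- NA
  etiology <- factor(sample(c("none", "alcohol", "hepB", "hepC", "other"), n,
                            replace = TRUE, prob = c(0.25, 0.32, 0.22, 0.1, 0.11)),
                     levels = clinical_levels$etiology)
  etiology[stats::runif(n) < 0.05] <- NA
  til <- factor(ifelse(stats::runif(n) < stats::plogis(config$til_logit_slope * h),
                       "positive", "negative"), levels = clinical_levels$til_status)

  clinical <- data.frame(sample_id = samples, age = age, sex = sex, stage = stage,
                         til_status = til, inflammation = inflammation,
                         etiology = etiology, stringsAsFactors = FALSE)

  ## --- censored endpoints ----------------------------------------------
  log_rr <- config$hazard_log_hr * h + config$exhaustion_hazard_log_hr * e
  for (ep in names(endpoint_multipliers)) {
    lam0 <- config$baseline_hazard * endpoint_multipliers[[ep]]
    rate <- lam0 * exp(log_rr)
    u_event <- stats::runif(n); u_cens <- stats::runif(n)
    t_event <- -log(u_event) / rate
    mu <- lam0 * config$censor_rate / (1 - config$censor_rate)
    t_cens <- -log(u_cens) / mu
    clinical[[paste0(ep, "_time")]] <- round(pmin(t_event, t_cens), 1)
    clinical[[paste0(ep, "_event")]] <- as.integer(t_event <= t_cens)
  }

  list(expression = expr, clinical = clinical, segments = segments,
       repertoire = repertoire,
       latent = data.frame(sample_id = samples, h = h, e = e,
                           stringsAsFactors = FALSE))
}

#' Planted immune-response gene set of a simulated cohort
#'
#' The PLANT genes carry the full heat loading, so together they form a
#' positive-control "immune response" gene set for the enrichment engine.
#'
#' @param config A `sim_config`.
#' @return Named list with one gene set (`PLANTED_IMMUNE_RESPONSE`).
#' @export
planted_gene_set <- function(config) {
  if (config$n_planted < 1L) ic_config_error("configuration has no planted genes")
  list(PLANTED_IMMUNE_RESPONSE = structure(
    sprintf("PLANT%03d", seq_len(config$n_planted)),
    description = "heat-loaded positive-control set"))
}

#' Write a simulated cohort to a directory
#'
#' Emits the exact file dialects the readers consume: `expression.tsv`,
#' `clinical.tsv`, `segments.seg`, `repertoire.tsv`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.seg"))
  write_repertoire(cohort$repertoire, file.path(dir, "repertoire.tsv"))
  invisible(dir)
}
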