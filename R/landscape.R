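#' Fit the immune landscape of a tumor cohort
#'
#' The central analysis of the package: computes per-sample immune scores
#' (CYT, APOBEC3 score, checkpoint index, HLA-A/B, SCNA events, repertoire
#' richness and CPK diversity), dichotomizes the cohort at the median of the
#' grouping score (CYT by default), compares demographics and scores between
#' the groups (Mann-Whitney / chi-square), optionally runs gene-set
#' enrichment between the groups, fits Kaplan-Meier curves with log-rank
#' tests for each endpoint, stratifies overall survival by the grouping
#' score crossed with each exhaustion marker, and runs a univariate Cox
#' screen followed by a multivariate model for overall survival.
#'
#' @param expr Gene x sample TPM matrix (see [read_expression_matrix()]).
#' @param clinical Clinical table (see [read_clinical()]).
#' @param segments Optional named list of segment profiles.
#' @param repertoire Optional repertoire summary data frame.
#' @param gene_sets Optional named list of gene sets for enrichment.
#' @param group_score Score used for dichotomization (default `"cyt"`).
#' @param endpoints Endpoints to analyze, subset of OS/DSS/PFI/DFI.
#' @param exhaustion_markers Genes whose median-split groups are crossed
#'   with the score groups for two-factor OS stratification.
#' @param cox_candidates Candidate covariates for the univariate screen.
#' @param alpha Univariate selection threshold.
#' @param cyt_pseudocount,log_pseudocount,thresholds Score parameters, see
#'   [build_score_frame()].
#' @param gsea_n_perm,gsea_perm_mode,gsea_weight Enrichment settings, see
#'   [gsea_analysis()].
#' @param seed Integer seed for the permutation procedures.
#' @return Object of class `immune_landscape`.
#' @examples
#' cohort <- generate_cohort(sim_config(n_samples = 80, seed = 1, n_decoy = 40))
#' fit <- immune_landscape(cohort$expression, cohort$clinical,
#'                         segments = cohort$segments,
#'                         repertoire = cohort$repertoire,
#'                         endpoints = "OS", gsea_n_perm = NULL)
#' print(fit)
#' @export
immune_landscape <- function(expr, clinical, segments = NULL, repertoire = NULL,
                             gene_sets = NULL, group_score = "cyt",
                             endpoints = c("OS", "DSS", "PFI", "DFI"),
                             exhaustion_markers = exhaustion_core_panel(),
                             cox_candidates = c("age", "sex", "stage", "etiology",
                                                "inflammation", "til_status", "group"),
                             alpha = 0.05,
                             cyt_pseudocount = 0.01, log_pseudocount = 1,
                             thresholds = scna_thresholds(),
                             gsea_n_perm = 1000, gsea_perm_mode = "auto",
                             gsea_weight = 1, seed = 1) {
  validate_expression_matrix(expr)
  endpoints <- match.arg(endpoints, c("OS", "DSS", "PFI", "DFI"), several.ok = TRUE)
  scores <- build_score_frame(expr, segments = segments, repertoire = repertoire,
                              cyt_pseudocount = cyt_pseudocount,
                              log_pseudocount = log_pseudocount,
                              thresholds = thresholds,
                              dichotomize = group_score)
  grp_col <- paste0(group_score, "_group")
  common <- intersect(scores$sample_id, clinical$sample_id)
  if (length(common) == 0L)
    ic_alignment_error("no overlap between expression and clinical sample ids")
  scores <- scores[match(common, scores$sample_id), , drop = FALSE]
  clin <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  merged <- cbind(scores, clin[setdiff(names(clin), "sample_id")])
  groups <- merged[[grp_col]]

  demo_feats <- intersect(c("age", "sex", "stage", "til_status", "inflammation",
                            "etiology"), names(merged))
  demographics <- compare_groups(merged, grp_col, demo_feats, mode = "normal")

  score_feats <- setdiff(c("apobec3", "checkpoint_index", "hla_a", "hla_b",
                           "scna_events", "tcr_richness", "bcr_richness", "cpk"),
                         group_score)
  score_tests <- compare_groups(merged, grp_col, score_feats, mode = "normal")

  gsea <- NULL
  if (!is.null(gene_sets) && !is.null(gsea_n_perm)) {
    gsea <- gsea_analysis(expr[, common, drop = FALSE], groups, gene_sets,
                          weight = gsea_weight, n_perm = gsea_n_perm,
                          perm_mode = gsea_perm_mode, seed = seed)
  }

  surv <- list()
  for (ep in endpoints) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!tcol %in% names(merged)) next
    ok <- !is.na(merged[[tcol]]) & !is.na(merged[[ecol]]) & !is.na(groups)
    if (!any(ok)) next
    surv[[ep]] <- list(
      fits = lapply(stats::setNames(nm = levels(groups)), function(g)
        km_fit(merged[[tcol]][ok & groups == g], merged[[ecol]][ok & groups == g])),
      logrank = log_rank(merged[[tcol]][ok], merged[[ecol]][ok], groups[ok]))
  }

  strat <- list()
  if ("OS_time" %in% names(merged) && length(exhaustion_markers)) {
    for (mk in exhaustion_markers) {
      sym <- if (mk %in% rownames(expr)) mk else unname(gene_aliases[mk])
      if (is.na(sym) || !sym %in% rownames(expr)) next
      mk_grp <- dichotomize_by_median(expr[sym, common])
      strat[[mk]] <- two_factor_stratification(
        merged$OS_time, merged$OS_event, groups, mk_grp,
        name_a = group_score, name_b = mk)
    }
  }

  cox <- NULL
  if ("OS_time" %in% names(merged)) {
    cdat <- merged
    cdat$group <- groups
    if ("til_status" %in% names(cdat))
      cdat$til_status <- stats::relevel(cdat$til_status, ref = "negative")
    cand <- intersect(cox_candidates, names(cdat))
    cand <- cand[vapply(cand, function(cn) {
      v <- cdat[[cn]][!is.na(cdat[[cn]])]
      length(unique(v)) >= 2L
    }, logical(1))]
    if (length(cand) && sum(merged$OS_event == 1, na.rm = TRUE) >= 1L) {
      cox <- univariate_screen_then_multivariate(
        merged$OS_time, merged$OS_event, cdat[cand], cand, alpha = alpha)
    }
  }

  structure(list(
    scores = scores, clinical = clin, groups = groups, group_score = group_score,
    demographics = demographics, score_tests = score_tests, gsea = gsea,
    survival = surv, stratification = strat, cox = cox,
    n = length(common), seed = seed, call = match.call()),
    class = "immune_landscape")
}

#' @export
print.immune_landscape <- function(x, ...) {
  cat(sprintf("Immune landscape fit: %d samples, grouped by %s (median split)\n",
              x$n, x$group_score))
  cat(sprintf("  %s-high: %d, %s-low: %d\n", x$group_score,
              sum(x$groups == "high", na.rm = TRUE), x$group_score,
              sum(x$groups == "low", na.rm = TRUE)))
  if (nrow(x$score_tests)) {
    cat("Score comparisons (high vs low):\n")
    st <- x$score_tests
    for (i in seq_len(nrow(st)))
      cat(sprintf("  %-18s p = %.3g\n", st$feature[i], st$p_value[i]))
  }
  for (ep in names(x$survival))
    cat(sprintf("%s log-rank p = %.3g\n", ep, x$survival[[ep]]$logrank$p_value))
  if (!is.null(x$cox) && !is.null(x$cox$multivariate)) {
    grow <- x$cox$multivariate$coefficients
    grow <- grow[grepl("^group", grow$term), , drop = FALSE]
    if (nrow(grow))
      cat(sprintf("Multivariate %s-high HR = %.3g (95%% CI %.3g-%.3g), p = %.3g\n",
                  x$group_score, grow$hr[1], grow$ci_low[1], grow$ci_high[1],
                  grow$wald_p[1]))
  }
  invisible(x)
}

#' @export
summary.immune_landscape <- function(object, ...) {
  print(object)
  if (nrow(object$demographics)) {
    cat("\nDemographics (high vs low):\n")
    print(object$demographics, row.names = FALSE)
  }
  if (!is.null(object$gsea)) {
    cat("\nTop enriched gene sets:\n")
    print(utils::head(as.data.frame(object$gsea)[c("set", "es", "nes", "nominal_p", "fdr_q")], 10),
          row.names = FALSE)
  }
  for (mk in names(object$stratification)) {
    cat(sprintf("\nOS stratified by %s x %s:\n", object$group_score, mk))
    print(object$stratification[[mk]])
  }
  if (!is.null(object$cox)) { cat("\n"); print(object$cox) }
  invisible(object)
}

#' @export
coef.immune_landscape <- function(object, ...) {
  if (is.null(object$cox) || is.null(object$cox$multivariate)) return(numeric(0))
  coef(object$cox$multivariate)
}

#' Plot Kaplan-Meier curves of an immune landscape fit
#'
#' Base-graphics step curves for the score-high and score-low groups of one
#' endpoint.
#'
#' @param x An `immune_landscape`.
#' @param endpoint Which endpoint to draw (default the first fitted).
#' @param col Two colors, low then high.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.immune_landscape <- function(x, endpoint = names(x$survival)[1],
                                  col = c("#D55E00", "#0072B2"), ...) {
  if (is.null(endpoint) || !endpoint %in% names(x$survival))
    ic_config_error("no fitted survival curves for endpoint '%s'", endpoint)
  fits <- x$survival[[endpoint]]$fits
  xmax <- max(unlist(lapply(fits, function(f) f$time)), 1)
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, 1),
                 xlab = "Months", ylab = "Survival probability",
                 main = sprintf("%s by %s group (log-rank p = %.3g)", endpoint,
                                x$group_score, x$survival[[endpoint]]$logrank$p_value), ...)
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    graphics::lines(stats::stepfun(f$time, c(1, f$surv)), do.points = FALSE,
                    col = col[i], lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(fits), col = col[seq_along(fits)],
                   lwd = 2, bty = "n")
  invisible(x)
}
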