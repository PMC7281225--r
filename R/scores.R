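#' Default gene panels
#'
#' `apobec3_panel()` is the seven-member APOBEC3 cytidine-deaminase family.
#' `checkpoint_panel()` is the full eleven-marker T-cell exhaustion panel
#' (PD-1, PD-L1, CTLA4, IDO1, IDO2, LAG3, TIM3, PD-L2, TIGIT, ADORA2A,
#' VISTA) under their HGNC symbols. `exhaustion_core_panel()` is the
#' four-marker subset (PD-1, CTLA4, PD-L1, LAG3) used for two-factor
#' survival stratification.
#'
#' @return Character vector of HGNC gene symbols.
#' @export
apobec3_panel <- function() {
  c("APOBEC3A", "APOBEC3B", "APOBEC3C", "APOBEC3D",
    "APOBEC3F", "APOBEC3G", "APOBEC3H")
}

#' @rdname apobec3_panel
#' @export
checkpoint_panel <- function() {
  c("PDCD1", "CD274", "CTLA4", "IDO1", "IDO2", "LAG3",
    "HAVCR2", "PDCD1LG2", "TIGIT", "ADORA2A", "VSIR")
}

#' @rdname apobec3_panel
#' @export
exhaustion_core_panel <- function() {
  c("PDCD1", "CTLA4", "CD274", "LAG3")
}

# Alias table: common literature names -> HGNC symbols. Applied only when the
# canonical symbol is absent from the matrix; never fuzzy.
gene_aliases <- c(
  "PD-1" = "PDCD1", "PD1" = "PDCD1", "PD-L1" = "CD274", "PDL1" = "CD274",
  "PD-L2" = "PDCD1LG2", "PDL2" = "PDCD1LG2", "TIM3" = "HAVCR2",
  "TIM-3" = "HAVCR2", "VISTA" = "VSIR")

require_genes <- function(expr, genes, what) {
  absent <- setdiff(genes, rownames(expr))
  if (length(absent))
    ic_missing_gene_error("%s: gene(s) absent from expression matrix: %s",
                          what, paste(absent, collapse = ", "))
  invisible(genes)
}

#' Cytolytic activity score (CYT)
#'
#' Geometric mean of GZMA and PRF1 expression in TPM per sample:
#' `exp(mean(log(TPM + pseudocount)))`. With `pseudocount = 0` and any zero
#' TPM the score is exactly 0.
#'
#' @param expr Gene x sample TPM matrix with GZMA and PRF1 rows.
#' @param pseudocount Non-negative value added inside the log (default 0.01).
#' @return Named numeric vector of per-sample CYT scores (TPM scale).
#' @export
cyt_score <- function(expr, pseudocount = 0.01) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L, pseudocount >= 0)
  require_genes(expr, c("GZMA", "PRF1"), "cyt_score")
  x <- expr[c("GZMA", "PRF1"), , drop = FALSE] + pseudocount
  if (pseudocount == 0 && any(x == 0)) {
    out <- exp(colMeans(log(x)))
    out[apply(x == 0, 2L, any)] <- 0
  } else {
    out <- exp(colMeans(log(x)))
  }
  out
}

#' Mean log2 expression over a gene panel
#'
#' Per sample, `mean(log2(TPM + pseudocount))` over the panel members. Used
#' for the APOBEC3 score and the immune inhibitory checkpoint index. Panel
#' members absent under their canonical symbol are resolved through a small
#' explicit alias table (PD-1 to PDCD1 and similar) before failing.
#'
#' @param expr Gene x sample TPM matrix.
#' @param panel Character vector of gene symbols.
#' @param pseudocount Positive value added before the log (default 1).
#' @return Named numeric vector of per-sample scores (log2 scale).
#' @export
log_average_score <- function(expr, panel, pseudocount = 1) {
  stopifnot(length(panel) >= 1L, is.numeric(pseudocount), pseudocount > 0)
  resolved <- vapply(panel, function(g) {
    if (g %in% rownames(expr)) return(g)
    alias <- unname(gene_aliases[g])
    if (!is.na(alias) && alias %in% rownames(expr)) return(alias)
    g
  }, character(1))
  require_genes(expr, resolved, "log_average_score")
  colMeans(log2(expr[resolved, , drop = FALSE] + pseudocount))
}

#' Median dichotomization into high/low groups
#'
#' Labels a sample "high" when its value is strictly greater than the cohort
#' median and "low" otherwise (ties at the median go to "low"). On tie-free
#' values this yields n/2 vs n/2 for even n and (n-1)/2 high vs (n+1)/2 low
#' for odd n; with 371 tie-free samples, 185 high and 186 low.
#'
#' @param values Named numeric vector, at least 2 values, no missing.
#' @return Factor with levels `low`, `high`, same names as `values`.
#' @export
dichotomize_by_median <- function(values) {
  if (length(values) < 2L)
    ic_degenerate_error("dichotomization needs at least 2 values, got %d", length(values))
  if (anyNA(values))
    ic_degenerate_error("dichotomization input contains missing values")
  med <- stats::median(values)
  factor(ifelse(values > med, "high", "low"), levels = c("low", "high"))
}

#' HLA-A / HLA-B expression extraction
#'
#' Raw TPM of the two class-I HLA genes, no transform.
#'
#' @param expr Gene x sample TPM matrix with `HLA-A` and `HLA-B` rows.
#' @return Data frame with columns `hla_a`, `hla_b`, row names sample ids.
#' @export
hla_expression <- function(expr) {
  require_genes(expr, c("HLA-A", "HLA-B"), "hla_expression")
  data.frame(hla_a = expr["HLA-A", ], hla_b = expr["HLA-B", ],
             row.names = colnames(expr))
}

#' Assemble the per-sample score frame
#'
#' Joins every per-sample immune score on the expression samples: CYT,
#' APOBEC3 score, checkpoint index, HLA-A/B TPM, SCNA event count, TCR/BCR
#' richness and CPK diversity. Samples missing a modality (no segment
#' profile, no repertoire row) get NA for the affected scores only. Group
#' labels (`<score>_group`) are attached by median dichotomization for each
#' name in `dichotomize`.
#'
#' @param expr Gene x sample TPM matrix.
#' @param segments Optional named list of per-sample segment data frames.
#' @param repertoire Optional repertoire summary data frame.
#' @param cyt_pseudocount Pseudocount for [cyt_score()].
#' @param log_pseudocount Pseudocount for [log_average_score()].
#' @param apobec_panel,chk_panel Gene panels for the APOBEC3 score and the
#'   checkpoint index.
#' @param thresholds SCNA thresholds from [scna_thresholds()].
#' @param dichotomize Character vector of score column names to dichotomize
#'   (default `"cyt"`); scores with missing values are dichotomized on their
#'   complete cases.
#' @return Data frame, one row per expression sample, with score columns and
#'   `<score>_group` factors; provenance (panels, pseudocounts, log base)
#'   recorded in the `"provenance"` attribute.
#' @export
build_score_frame <- function(expr, segments = NULL, repertoire = NULL,
                              cyt_pseudocount = 0.01, log_pseudocount = 1,
                              apobec_panel = apobec3_panel(),
                              chk_panel = checkpoint_panel(),
                              thresholds = scna_thresholds(),
                              dichotomize = "cyt") {
  validate_expression_matrix(expr)
  samples <- colnames(expr)
  frame <- data.frame(
    sample_id = samples,
    cyt = unname(cyt_score(expr, cyt_pseudocount)),
    apobec3 = unname(log_average_score(expr, apobec_panel, log_pseudocount)),
    checkpoint_index = unname(log_average_score(expr, chk_panel, log_pseudocount)),
    stringsAsFactors = FALSE)
  hla <- hla_expression(expr)
  frame$hla_a <- hla$hla_a
  frame$hla_b <- hla$hla_b

  frame$scna_events <- NA_integer_
  if (!is.null(segments)) {
    hit <- intersect(samples, names(segments))
    if (length(hit) == 0L)
      ic_alignment_error("no overlap between expression samples and segment profiles")
    frame$scna_events[match(hit, samples)] <-
      vapply(segments[hit], scna_event_count, integer(1), thr = thresholds)
  }

  frame$tcr_richness <- NA_integer_
  frame$bcr_richness <- NA_integer_
  frame$cpk <- NA_real_
  if (!is.null(repertoire)) {
    hit <- intersect(samples, repertoire$sample_id)
    if (length(hit) == 0L)
      ic_alignment_error("no overlap between expression samples and repertoire table")
    idx <- match(hit, repertoire$sample_id)
    at <- match(hit, samples)
    frame$tcr_richness[at] <- repertoire$tcr_unique_cdr3[idx]
    frame$bcr_richness[at] <- repertoire$bcr_unique_clonotypes[idx]
    ok <- repertoire$tcr_total_reads[idx] > 0L
    frame$cpk[at[ok]] <- 1000 * repertoire$tcr_unique_cdr3[idx][ok] /
      repertoire$tcr_total_reads[idx][ok]
  }

  for (sc in dichotomize) {
    if (!sc %in% names(frame)) ic_config_error("cannot dichotomize unknown score '%s'", sc)
    v <- frame[[sc]]
    grp <- factor(rep(NA_character_, nrow(frame)), levels = c("low", "high"))
    ok <- !is.na(v)
    if (sum(ok) >= 2L) grp[ok] <- dichotomize_by_median(v[ok])
    frame[[paste0(sc, "_group")]] <- grp
  }
  rownames(frame) <- samples
  attr(frame, "provenance") <- list(
    cyt_pseudocount = cyt_pseudocount, log_pseudocount = log_pseudocount,
    log_base = 2, apobec_panel = apobec_panel, checkpoint_panel = chk_panel,
    scna_gain_min = thresholds$gain_min, scna_loss_max = thresholds$loss_max,
    dichotomized = dichotomize)
  frame
}

#' Write a score frame as TSV with a provenance header
#'
#' The commented header records panel membership, pseudocounts and log base
#' so any downstream consumer can see how the scores were defined.
#'
#' @param frame Score frame from [build_score_frame()].
#' @param path Output path.
#' @export
write_score_frame <- function(frame, path) {
  prov <- attr(frame, "provenance")
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(prov)) {
    writeLines(c(
      sprintf("# cyt_pseudocount=%g log_pseudocount=%g log_base=%d",
              prov$cyt_pseudocount, prov$log_pseudocount, prov$log_base),
      sprintf("# apobec_panel=%s", paste(prov$apobec_panel, collapse = ",")),
      sprintf("# checkpoint_panel=%s", paste(prov$checkpoint_panel, collapse = ",")),
      sprintf("# scna_thresholds=[%g,%g] cpk_scale=1000",
              prov$scna_loss_max, prov$scna_gain_min)), con)
  }
  out <- frame
  for (col in names(out)) if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
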