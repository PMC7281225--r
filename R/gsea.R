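# Gene-set enrichment engine: signal-to-noise ranking, weighted
# Kolmogorov-Smirnov running sum, permutation null for NES / nominal p, and
# ratio-of-tails FDR over pooled normalized nulls.

# Signal-to-noise on a log2 matrix given a logical high-group mask.
# Each group sd is floored at max(min_sd, 0.2 * |group mean|).
s2n_metric <- function(logmat, ishigh, min_sd = 0.2) {
  hi <- logmat[, ishigh, drop = FALSE]
  lo <- logmat[, !ishigh, drop = FALSE]
  m1 <- rowMeans(hi); m0 <- rowMeans(lo)
  s1 <- sqrt(rowSums((hi - m1)^2) / (ncol(hi) - 1L))
  s0 <- sqrt(rowSums((lo - m0)^2) / (ncol(lo) - 1L))
  s1 <- pmax(s1, min_sd, 0.2 * abs(m1))
  s0 <- pmax(s0, min_sd, 0.2 * abs(m0))
  (m1 - m0) / (s1 + s0)
}

#' Rank genes by signal-to-noise between two groups
#'
#' Computes the per-gene signal-to-noise ratio
#' (mean_high - mean_low) / (sd_high + sd_low) on log2(TPM + 1), with each
#' group standard deviation floored at `max(min_sd, 0.2 * |group mean|)`,
#' and sorts descending. Ties are broken by gene symbol so the ordering is
#' deterministic.
#'
#' @param expr Gene x sample TPM matrix.
#' @param groups Factor with levels `low`, `high` aligned with the samples.
#' @param min_sd Absolute floor on each group standard deviation.
#' @return Object of class `ranked_list`: `genes` (descending order) and
#'   `metric` (named, same order).
#' @export
rank_genes <- function(expr, groups, min_sd = 0.2) {
  groups <- factor(groups, levels = c("low", "high"))
  if (length(groups) != ncol(expr))
    ic_config_error("groups length (%d) must match sample count (%d)",
                    length(groups), ncol(expr))
  ok <- !is.na(groups)
  if (sum(groups[ok] == "high") < 2L || sum(groups[ok] == "low") < 2L)
    ic_degenerate_error("signal-to-noise ranking needs at least 2 samples per group")
  logmat <- log2(expr[, ok, drop = FALSE] + 1)
  metric <- s2n_metric(logmat, groups[ok] == "high", min_sd)
  ord <- order(-metric, rownames(expr))
  structure(list(genes = rownames(expr)[ord],
                 metric = stats::setNames(metric[ord], rownames(expr)[ord])),
            class = "ranked_list")
}

#' Weighted KS running-sum enrichment score
#'
#' Walks the ranked list; at a set member ("hit") the sum rises by
#' `|metric|^weight / sum of hit weights`, at a non-member it falls by
#' `1 / (N - N_hits)`. The enrichment score is the signed value of maximal
#' absolute deviation from zero; the leading edge holds the hit members at
#' or before the extremum (at or after it for a negative ES). The walk ends
#' at zero by construction. If every hit metric is zero under a positive
#' weight, hits are weighted uniformly.
#'
#' @param ranked A `ranked_list` from [rank_genes()].
#' @param set Character vector of gene symbols (members absent from the
#'   ranked list are ignored; no overlap at all is an error).
#' @param weight Exponent on `|metric|` (default 1, the classic weighted
#'   statistic; 0 gives the unweighted KS walk).
#' @return List with `es`, `running_sum` (length N), `leading_edge`,
#'   `peak` (index of the extremum), `n_hits`.
#' @export
enrichment_score <- function(ranked, set, weight = 1) {
  genes <- ranked$genes
  n <- length(genes)
  hit <- genes %in% set
  nh <- sum(hit)
  if (nh == 0L)
    ic_stop("immunocyt_no_overlap_error", "gene set has no overlap with the ranked list")
  if (nh == n) {
    walk <- cumsum(abs(ranked$metric)^weight)
    walk <- walk / walk[n]
    peak <- which.max(abs(walk))
    return(list(es = unname(walk[peak]), running_sum = unname(walk),
                leading_edge = genes, peak = peak, n_hits = nh))
  }
  w <- abs(ranked$metric)^weight
  w[!hit] <- 0
  tot <- sum(w)
  if (tot == 0) { w[hit] <- 1; tot <- nh }  # degenerate all-zero metric
  inc <- w / tot
  dec <- (!hit) / (n - nh)
  walk <- cumsum(inc - dec)
  peak <- which.max(abs(walk))
  es <- walk[peak]
  le <- if (es >= 0) genes[hit & seq_len(n) <= peak] else genes[hit & seq_len(n) >= peak]
  list(es = unname(es), running_sum = unname(walk), leading_edge = le,
       peak = peak, n_hits = nh)
}

#' Permutation normalization and significance for one gene set
#'
#' Builds a null ES distribution by permutation: `gene_set` mode draws
#' random member sets of equal size from the ranked list; `phenotype` mode
#' shuffles the group labels and re-ranks (requires `expr` and `groups`).
#' NES is the observed ES divided by the mean |null ES| of matching sign;
#' the nominal p is the same-sign tail fraction with an add-one correction.
#'
#' @param ranked A `ranked_list`.
#' @param set Gene symbols of the set.
#' @param n_perm Number of permutations (>= 100).
#' @param perm_mode `"gene_set"` or `"phenotype"`.
#' @param weight Running-sum weight.
#' @param expr,groups Required for `phenotype` mode.
#' @param min_sd Passed to the re-ranking in `phenotype` mode.
#' @param seed Optional integer seed for the permutations.
#' @return List of class `gsea_result` with `es`, `nes`, `nominal_p`,
#'   `leading_edge`, `n_permutations`, `perm_mode` and the `null_es` vector.
#' @export
normalize_and_test <- function(ranked, set, n_perm = 1000,
                               perm_mode = c("gene_set", "phenotype"),
                               weight = 1, expr = NULL, groups = NULL,
                               min_sd = 0.2, seed = NULL) {
  perm_mode <- match.arg(perm_mode)
  if (n_perm < 100L) ic_config_error("at least 100 permutations required, got %d", n_perm)
  if (!is.null(seed)) set.seed(seed)
  obs <- enrichment_score(ranked, set, weight)
  nh <- obs$n_hits
  null_es <- if (perm_mode == "gene_set") {
    vapply(seq_len(n_perm), function(b)
      enrichment_score(ranked, sample(ranked$genes, nh), weight)$es, numeric(1))
  } else {
    if (is.null(expr) || is.null(groups))
      ic_config_error("phenotype permutation mode requires expr and groups")
    g <- factor(groups, levels = c("low", "high"))
    logmat <- log2(expr + 1)
    vapply(seq_len(n_perm), function(b) {
      perm <- sample(g)
      metric <- s2n_metric(logmat, perm == "high", min_sd)
      ord <- order(-metric, rownames(expr))
      rl <- structure(list(genes = rownames(expr)[ord],
                           metric = stats::setNames(metric[ord], rownames(expr)[ord])),
                      class = "ranked_list")
      enrichment_score(rl, set, weight)$es
    }, numeric(1))
  }
  structure(c(score_vs_null(obs$es, null_es),
              list(leading_edge = obs$leading_edge, n_hits = nh,
                   n_permutations = n_perm, perm_mode = perm_mode,
                   null_es = null_es)),
            class = "gsea_result")
}

# NES and nominal p of an observed ES against its permutation null.
score_vs_null <- function(es, null_es) {
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  list(es = es, nes = nes, nominal_p = p)
}

#' Gene-set enrichment over a collection
#'
#' Ranks once, scores every set, and computes NES, nominal p and FDR q. The
#' permutation mode defaults to phenotype label shuffling when both groups
#' have at least 7 samples, else to random gene sets; phenotype permutations
#' are shared across sets. Set members absent from the expression matrix are
#' dropped with a message. FDR uses the ratio-of-tails estimator over the
#' pooled normalized null distributions of all sets.
#'
#' @param expr Gene x sample TPM matrix.
#' @param groups Factor with levels `low`, `high` aligned with samples.
#' @param sets Named list of gene-symbol vectors (e.g. from
#'   [read_gene_sets()]).
#' @param weight Running-sum weight (default 1).
#' @param n_perm Permutations per set (>= 100).
#' @param perm_mode `"auto"`, `"gene_set"` or `"phenotype"`.
#' @param min_sd Signal-to-noise sd floor.
#' @param seed Integer seed for the permutations.
#' @return Data frame of class `gsea_table`: one row per scored set with
#'   `set`, `size`, `es`, `nes`, `nominal_p`, `fdr_q`, `leading_edge`,
#'   `n_permutations`, `perm_mode`.
#' @export
gsea_analysis <- function(expr, groups, sets, weight = 1, n_perm = 1000,
                          perm_mode = c("auto", "gene_set", "phenotype"),
                          min_sd = 0.2, seed = 1) {
  perm_mode <- match.arg(perm_mode)
  if (n_perm < 100L) ic_config_error("at least 100 permutations required, got %d", n_perm)
  groups <- factor(groups, levels = c("low", "high"))
  if (perm_mode == "auto")
    perm_mode <- if (min(table(groups)) >= 7L) "phenotype" else "gene_set"
  ranked <- rank_genes(expr, groups, min_sd)
  kept <- lapply(sets, function(s) intersect(s, ranked$genes))
  dropped <- sum(lengths(sets) - lengths(kept))
  if (dropped > 0)
    message(sprintf("gsea_analysis: %d set member(s) absent from the expression matrix dropped", dropped))
  kept <- kept[lengths(kept) > 0L]
  if (length(kept) == 0L)
    ic_stop("immunocyt_no_overlap_error", "no gene set overlaps the expression matrix")

  set.seed(seed)
  obs <- lapply(kept, enrichment_score, ranked = ranked, weight = weight)

  nulls <- if (perm_mode == "gene_set") {
    lapply(obs, function(o)
      vapply(seq_len(n_perm), function(b)
        enrichment_score(ranked, sample(ranked$genes, o$n_hits), weight)$es, numeric(1)))
  } else {
    ok <- !is.na(groups)
    logmat <- log2(expr[, ok, drop = FALSE] + 1)
    g <- groups[ok]
    null_mat <- matrix(NA_real_, nrow = n_perm, ncol = length(kept))
    for (b in seq_len(n_perm)) {
      perm <- sample(g)
      metric <- s2n_metric(logmat, perm == "high", min_sd)
      ord <- order(-metric, rownames(expr))
      rl <- structure(list(genes = rownames(expr)[ord],
                           metric = stats::setNames(metric[ord], rownames(expr)[ord])),
                      class = "ranked_list")
      null_mat[b, ] <- vapply(kept, function(s) enrichment_score(rl, s, weight)$es,
                              numeric(1))
    }
    lapply(seq_along(kept), function(j) null_mat[, j])
  }

  stats_list <- Map(function(o, ne) score_vs_null(o$es, ne), obs, nulls)
  nes <- vapply(stats_list, `[[`, numeric(1), "nes")
  # normalize each set's null the same way its observed ES was normalized
  null_nes <- unlist(lapply(seq_along(kept), function(j) {
    ne <- nulls[[j]]
    pos <- ne[ne >= 0]; neg <- ne[ne < 0]
    c(if (length(pos)) pos / mean(pos) else numeric(0),
      if (length(neg)) neg / mean(abs(neg)) else numeric(0))
  }), use.names = FALSE)
  fdr_q <- vapply(nes, function(v) fdr_ratio_of_tails(v, nes, null_nes), numeric(1))

  out <- data.frame(
    set = names(kept), size = lengths(kept),
    es = vapply(obs, `[[`, numeric(1), "es"),
    nes = nes,
    nominal_p = vapply(stats_list, `[[`, numeric(1), "nominal_p"),
    fdr_q = fdr_q,
    leading_edge = vapply(obs, function(o) paste(o$leading_edge, collapse = ","), character(1)),
    n_permutations = n_perm, perm_mode = perm_mode,
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$nes), ]
  rownames(out) <- NULL
  attr(out, "null_nes") <- null_nes
  class(out) <- c("gsea_table", "data.frame")
  out
}

# Ratio-of-tails FDR: tail fraction of the pooled normalized null at this
# NES over the matching tail fraction of the observed NES values.
fdr_ratio_of_tails <- function(nes, all_obs_nes, null_nes) {
  if (is.na(nes)) return(NA_real_)
  if (nes >= 0) {
    num_den <- sum(null_nes >= 0)
    num <- if (num_den) sum(null_nes >= nes) / num_den else 0
    obs_den <- sum(all_obs_nes >= 0, na.rm = TRUE)
    den <- if (obs_den) sum(all_obs_nes >= nes, na.rm = TRUE) / obs_den else 1
  } else {
    num_den <- sum(null_nes < 0)
    num <- if (num_den) sum(null_nes <= nes) / num_den else 0
    obs_den <- sum(all_obs_nes < 0, na.rm = TRUE)
    den <- if (obs_den) sum(all_obs_nes <= nes, na.rm = TRUE) / obs_den else 1
  }
  min(1, num / max(den, .Machine$double.eps))
}

#' Write a GSEA results table as TSV
#' @param tab A `gsea_table` from [gsea_analysis()].
#' @param path Output path.
#' @export
write_gsea_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
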