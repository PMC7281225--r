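#' SCNA calling thresholds
#'
#' A segment is an SCNA event when its log2 segment mean is at or above
#' `gain_min` (amplification) or at or below `loss_max` (deletion);
#' boundaries inclusive.
#'
#' @param gain_min Positive gain threshold (default 0.6).
#' @param loss_max Negative loss threshold (default -0.4).
#' @return List with elements `gain_min`, `loss_max`.
#' @export
scna_thresholds <- function(gain_min = 0.6, loss_max = -0.4) {
  if (!(gain_min > 0 && loss_max < 0))
    ic_config_error("SCNA thresholds require gain_min > 0 > loss_max (got %g, %g)",
                    gain_min, loss_max)
  list(gain_min = gain_min, loss_max = loss_max)
}

#' Count SCNA events in a segment profile
#'
#' Counts segments whose log2 segment mean qualifies under the thresholds.
#' `mode = "magnitude"` instead sums the absolute segment means of
#' qualifying segments; counting is the default.
#'
#' @param profile Data frame of segments with a `seg_mean` column (as
#'   returned per sample by [read_segments()]); may have zero rows.
#' @param thr Thresholds from [scna_thresholds()].
#' @param mode `"count"` (default) or `"magnitude"`.
#' @return Integer event count (or numeric magnitude sum).
#' @export
scna_event_count <- function(profile, thr = scna_thresholds(), mode = c("count", "magnitude")) {
  mode <- match.arg(mode)
  if (is.null(profile) || nrow(profile) == 0L)
    return(if (mode == "count") 0L else 0)
  hit <- profile$seg_mean >= thr$gain_min | profile$seg_mean <= thr$loss_max
  if (mode == "count") sum(hit) else sum(abs(profile$seg_mean[hit]))
}

#' TCR / BCR repertoire richness
#'
#' Richness is the number of distinct clonotypes: unique CDR3 count for the
#' T-cell receptor, unique clonotype count for the B-cell receptor.
#'
#' @param rep One-row repertoire record (list or data frame row) with fields
#'   `tcr_unique_cdr3`, `tcr_total_reads`, `bcr_unique_clonotypes`.
#' @return Integer clonotype count.
#' @export
tcr_richness <- function(rep) as.integer(rep$tcr_unique_cdr3)

#' @rdname tcr_richness
#' @export
bcr_richness <- function(rep) as.integer(rep$bcr_unique_clonotypes)

#' TCR diversity in clonotypes per kilo-reads (CPK)
#'
#' `1000 * tcr_unique_cdr3 / tcr_total_reads`; always in [0, 1000] since a
#' sample cannot carry more clonotypes than reads. Undefined (an error, not
#' zero) when the read count is zero.
#'
#' @inheritParams tcr_richness
#' @return CPK diversity value.
#' @export
cpk_diversity <- function(rep) {
  if (is.na(rep$tcr_total_reads) || rep$tcr_total_reads <= 0L)
    ic_degenerate_error("CPK diversity undefined: zero total TCR reads for sample %s",
                        if (!is.null(rep$sample_id)) rep$sample_id else "<unknown>")
  1000 * rep$tcr_unique_cdr3 / rep$tcr_total_reads
}
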