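#' Read a gene-by-sample TPM expression matrix
#'
#' Reads a tab-separated file whose first column holds gene symbols and whose
#' header row holds sample identifiers; the body must be non-negative numeric
#' TPM values. The result is a base numeric matrix with gene symbols as row
#' names and sample ids as column names.
#'
#' @param path Path to a tab-separated text file.
#' @return A numeric matrix (genes x samples) of TPM values.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) ic_format_error("empty expression file: %s", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples))
    ic_duplicate_error("duplicate sample id in %s: %s", path,
                       paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  genes <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(samples) + 1L)
      ic_parse_error("line %d of %s: expected %d fields, found %d",
                     i + 1L, path, length(samples) + 1L, length(fields))
    genes[i] <- fields[[1L]]
    row <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(row)) {
      bad <- which(is.na(row))[1L]
      ic_parse_error("line %d of %s: non-numeric value '%s' for gene %s, sample %s",
                     i + 1L, path, fields[bad + 1L], fields[[1L]], samples[bad])
    }
    values[i, ] <- row
  }
  dimnames(values) <- list(genes, samples)
  validate_expression_matrix(values)
  values
}

#' @keywords internal
validate_expression_matrix <- function(x) {
  genes <- rownames(x); samples <- colnames(x)
  if (is.null(genes) || is.null(samples))
    ic_format_error("expression matrix must carry gene row names and sample column names")
  if (anyDuplicated(genes))
    ic_duplicate_error("duplicate gene symbol: %s",
                       paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    ic_duplicate_error("duplicate sample id: %s",
                       paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(x)) ic_format_error("expression matrix contains missing values")
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1L, ]
    ic_format_error("negative TPM value for gene %s, sample %s",
                    genes[idx[[1L]]], samples[idx[[2L]]])
  }
  invisible(x)
}

#' Write an expression matrix as tab-separated text
#'
#' Emits the same dialect [read_expression_matrix()] consumes; writing then
#' reading reproduces the matrix exactly.
#'
#' @param x Numeric gene x sample matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(x, path) {
  validate_expression_matrix(x)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE, scientific = FALSE)),
          collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read copy-number segments in SEG layout
#'
#' Expects tab-separated columns `sample`, `chrom`, `loc.start`, `loc.end`,
#' `num.mark`, `seg.mean` (TCGA SEG convention: 1-based, inclusive on both
#' ends; `seg.mean` is a log2 copy ratio). Rows are grouped by sample into one
#' segment profile per distinct sample id.
#'
#' @param path Path to a SEG-style tab-separated file.
#' @return A named list of data frames, one per sample, each with columns
#'   `chrom`, `start`, `end`, `num_markers`, `seg_mean`.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  if (ncol(df) < 6L) ic_format_error("SEG file %s needs 6 columns, found %d", path, ncol(df))
  names(df)[1:6] <- c("sample", "chrom", "start", "end", "num_markers", "seg_mean")
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      ic_parse_error("row %d of %s: non-numeric %s '%s'", bad, path, what, df[[col]][bad])
    }
    v
  }
  start <- num("start", "start"); end <- num("end", "end")
  nm <- num("num_markers", "marker count"); sm <- num("seg_mean", "segment mean")
  if (any(end < start)) {
    bad <- which(end < start)[1L]
    ic_format_error("row %d of %s: segment end %s < start %s (sample %s)",
                    bad, path, format(end[bad]), format(start[bad]), df$sample[bad])
  }
  if (any(nm <= 0 | nm != round(nm)))
    ic_format_error("row %d of %s: marker count must be a positive integer",
                    which(nm <= 0 | nm != round(nm))[1L], path)
  seg <- data.frame(chrom = df$chrom, start = start, end = end,
                    num_markers = as.integer(nm), seg_mean = sm,
                    stringsAsFactors = FALSE)
  out <- split(seg, factor(df$sample, levels = unique(df$sample)))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Write segment profiles as SEG-style text
#' @param profiles Named list of per-sample segment data frames.
#' @param path Output path.
#' @export
write_segments <- function(profiles, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("sample\tchrom\tloc.start\tloc.end\tnum.mark\tseg.mean", con)
  for (sid in names(profiles)) {
    d <- profiles[[sid]]
    if (nrow(d) == 0L) next
    writeLines(paste(sid, d$chrom,
                     format(d$start, scientific = FALSE, trim = TRUE),
                     format(d$end, scientific = FALSE, trim = TRUE),
                     d$num_markers,
                     format(d$seg_mean, digits = 15, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name <TAB> description <TAB> member1 <TAB> member2 ...`.
#' Memberships are de-duplicated; duplicate set names are rejected.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene symbols; each element
#'   carries a `description` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      ic_parse_error("line %d of %s: GMT line needs name, description and at least one member", i, path)
    nms[i] <- fields[[1L]]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      ic_parse_error("line %d of %s: gene set %s has no members", i, path, fields[[1L]])
    sets[[i]] <- structure(members, description = fields[[2L]])
  }
  if (anyDuplicated(nms))
    ic_duplicate_error("duplicate gene set name: %s",
                       paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

#' Write gene sets in GMT layout
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute).
#' @param path Output path.
#' @export
write_gene_sets <- function(sets, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(sets)) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    writeLines(paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t"), con)
  }
  invisible(path)
}

# Column dictionary mapping clinical file headers to canonical field names.
clinical_columns <- c(
  sample_id = "sample_id", age = "age", sex = "sex", stage = "stage",
  til_status = "til_status", inflammation = "inflammation", etiology = "etiology",
  OS_time = "OS_time", OS_event = "OS_event", DSS_time = "DSS_time",
  DSS_event = "DSS_event", PFI_time = "PFI_time", PFI_event = "PFI_event",
  DFI_time = "DFI_time", DFI_event = "DFI_event")

clinical_levels <- list(
  sex = c("male", "female"),
  stage = c("I", "II", "III", "IV"),
  til_status = c("positive", "negative"),
  inflammation = c("none", "mild", "severe"),
  etiology = c("none", "alcohol", "hepB", "hepC", "other"))

#' Read a clinical cohort table
#'
#' Tab-separated with a header; the `sample_id` column is mandatory.
#' Recognised columns: `age`, `sex`, `stage`, `til_status`, `inflammation`,
#' `etiology` and the four endpoint pairs `OS/DSS/PFI/DFI` as
#' `<endpoint>_time` (months) plus `<endpoint>_event` (1 observed,
#' 0 censored). Unknown category labels become missing with a warning;
#' missing values are a first-class category and are never imputed.
#'
#' @param path Path to a tab-separated clinical table.
#' @return A data frame with canonical column names; categorical columns are
#'   factors with the declared level sets.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                          colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% names(df))
    ic_format_error("clinical table %s lacks a sample_id column", path)
  keep <- intersect(names(clinical_columns), names(df))
  df <- df[keep]
  if (anyDuplicated(df$sample_id))
    ic_duplicate_error("duplicate sample id in clinical table: %s",
                       df$sample_id[duplicated(df$sample_id)][1L])
  for (col in intersect(names(clinical_levels), names(df))) {
    lev <- clinical_levels[[col]]
    raw <- df[[col]]
    bad <- !is.na(raw) & !(raw %in% lev)
    if (any(bad)) {
      warning(sprintf("clinical column %s: %d unknown value(s) (e.g. '%s') set to missing",
                      col, sum(bad), raw[bad][1L]), call. = FALSE)
      raw[bad] <- NA
    }
    df[[col]] <- factor(raw, levels = lev)
  }
  if ("age" %in% names(df)) {
    df$age <- suppressWarnings(as.numeric(df$age))
  }
  for (ep in c("OS", "DSS", "PFI", "DFI")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (!tcol %in% names(df)) next
    tv <- suppressWarnings(as.numeric(df[[tcol]]))
    ev <- if (ecol %in% names(df)) suppressWarnings(as.numeric(df[[ecol]])) else rep(NA_real_, nrow(df))
    if (any(!is.na(tv) & tv < 0))
      ic_format_error("negative %s time for sample %s", ep, df$sample_id[which(!is.na(tv) & tv < 0)[1L]])
    if (any(!is.na(ev) & !(ev %in% c(0, 1))))
      ic_format_error("%s event flag must be 0 or 1 (sample %s)", ep,
                      df$sample_id[which(!is.na(ev) & !(ev %in% c(0, 1)))[1L]])
    mism <- xor(is.na(tv), is.na(ev))
    if (any(mism))
      ic_format_error("%s time/event pair incomplete for sample %s", ep,
                      df$sample_id[which(mism)[1L]])
    df[[tcol]] <- tv
    df[[ecol]] <- as.integer(ev)
  }
  n_missing <- vapply(df, function(x) sum(is.na(x)), integer(1))
  attr(df, "n_missing") <- n_missing
  df
}

#' Write a clinical cohort table
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  for (col in names(out)) if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a repertoire summary table
#'
#' Tab-separated with columns `sample_id`, `tcr_unique_cdr3`,
#' `tcr_total_reads`, `bcr_unique_clonotypes` (non-negative integers). A
#' sample with positive read count cannot report more unique CDR3 clonotypes
#' than reads.
#'
#' @param path Path to a tab-separated repertoire table.
#' @return Data frame with the four canonical columns.
#' @export
read_repertoire <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("sample_id", "tcr_unique_cdr3", "tcr_total_reads", "bcr_unique_clonotypes")
  miss <- setdiff(need, names(df))
  if (length(miss)) ic_format_error("repertoire table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    ic_duplicate_error("duplicate sample id in repertoire table: %s",
                       df$sample_id[duplicated(df$sample_id)][1L])
  for (col in need[-1]) {
    v <- df[[col]]
    if (!is.numeric(v) || any(!is.na(v) & (v < 0 | v != round(v))))
      ic_format_error("repertoire column %s must hold non-negative integers", col)
    df[[col]] <- as.integer(v)
  }
  bad <- !is.na(df$tcr_total_reads) & df$tcr_total_reads > 0L &
    df$tcr_unique_cdr3 > df$tcr_total_reads
  if (any(bad))
    ic_format_error("sample %s: unique CDR3 count exceeds total TCR reads",
                    df$sample_id[which(bad)[1L]])
  df
}

#' Write a repertoire summary table
#' @param rep Data frame as returned by [read_repertoire()].
#' @param path Output path.
#' @export
write_repertoire <- function(rep, path) {
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
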