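#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The U statistic counts pairs with `x > y` plus
#' half the tied pairs. In `exact` mode (the default for combined n <= 12)
#' the p-value is computed by full enumeration of all `choose(n, n_x)`
#' assignments of the pooled values to the two groups, which remains valid
#' under ties. In `normal` mode a Gaussian approximation with tie-corrected
#' variance and continuity correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"auto"` (exact when `length(x) + length(y) <= 12`),
#'   `"exact"` or `"normal"`.
#' @return List of class `ic_test` with `statistic` (U for `x` vs `y`),
#'   `p_value`, `method` (`mwu_exact` / `mwu_normal`) and `n_per_group`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L)
    ic_degenerate_error("Mann-Whitney requires two non-empty groups (n = %d, %d)", nx, ny)
  if (mode == "auto") mode <- if (nx + ny <= 12L) "exact" else "normal"
  u <- mwu_u(x, y)
  mu <- nx * ny / 2
  if (mode == "exact") {
    pooled <- c(x, y)
    combos <- utils::combn(nx + ny, nx)
    us <- apply(combos, 2L, function(idx) mwu_u(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "mwu_exact"
  } else {
    n <- nx + ny
    ties <- table(c(x, y))
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1  # all values tied: no evidence either way
    } else {
      z <- (abs(u - mu) - 0.5) / sqrt(v)
      z <- max(z, 0)
      p <- 2 * stats::pnorm(-z)
    }
    p <- min(p, 1)
    method <- "mwu_normal"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n_per_group = c(nx, ny)), class = "ic_test")
}

mwu_u <- function(x, y) {
  # U = #{(i,j): x_i > y_j} + 0.5 #ties, via the rank-sum identity
  nx <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction on an r x c table of
#' non-negative counts; df = (r-1)(c-1), p from the chi-square upper tail.
#'
#' @param table Matrix of non-negative integer counts; all row and column
#'   marginals must be positive.
#' @return List of class `ic_test` with `statistic`, `p_value`, `df`,
#'   `method = "chi_square"` and `n_per_group` (row sums).
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    ic_format_error("contingency table must hold non-negative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    ic_degenerate_error("contingency table has a zero marginal")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
                 df = unname(ht$parameter), method = "chi_square",
                 n_per_group = rowSums(table)), class = "ic_test")
}

#' @export
print.ic_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n = %s)\n",
              x$method, x$statistic, x$p_value,
              paste(x$n_per_group, collapse = "/")))
  invisible(x)
}

#' Compare features between score-defined groups
#'
#' For each feature, numeric columns are compared between the two groups with
#' the Mann-Whitney test and categorical columns with the chi-square test on
#' the group x category contingency table. Missing values are dropped
#' pairwise per feature; a feature that is entirely missing (or categorical
#' with a degenerate table) is skipped with a warning.
#'
#' @param frame Score frame (or any data frame) holding the features.
#' @param group_by Name of the grouping column (a two-level factor, e.g.
#'   `"cyt_group"`), or a factor vector aligned with `frame`.
#' @param features Character vector of column names to test.
#' @param mode Mann-Whitney mode passed to [mann_whitney()].
#' @param fdr If TRUE, append Benjamini-Hochberg adjusted q-values.
#' @return Data frame with columns `feature`, `statistic`, `p_value`,
#'   `method`, `n_low`, `n_high` (and `q_value` when `fdr`).
#' @export
compare_groups <- function(frame, group_by, features, mode = "auto", fdr = FALSE) {
  grp <- if (is.character(group_by) && length(group_by) == 1L) {
    if (!group_by %in% names(frame)) ic_config_error("unknown grouping column '%s'", group_by)
    frame[[group_by]]
  } else group_by
  grp <- factor(grp)
  if (nlevels(grp) != 2L)
    ic_degenerate_error("compare_groups requires exactly 2 group levels, got %d", nlevels(grp))
  unknown <- setdiff(features, names(frame))
  if (length(unknown)) ic_config_error("unknown feature(s): %s", paste(unknown, collapse = ", "))
  rows <- lapply(features, function(f) {
    v <- frame[[f]]
    ok <- !is.na(v) & !is.na(grp)
    if (!any(ok)) {
      warning(sprintf("feature %s has no non-missing values; skipped", f), call. = FALSE)
      return(NULL)
    }
    v <- v[ok]; g <- droplevels(grp[ok])
    if (nlevels(g) < 2L) {
      warning(sprintf("feature %s observed in one group only; skipped", f), call. = FALSE)
      return(NULL)
    }
    lows <- v[g == levels(g)[1L]]; highs <- v[g == levels(g)[2L]]
    if (is.numeric(v)) {
      ht <- mann_whitney(highs, lows, mode = mode)
    } else {
      tab <- table(g, factor(v))
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2L) {
        warning(sprintf("feature %s has fewer than 2 observed categories; skipped", f),
                call. = FALSE)
        return(NULL)
      }
      ht <- chi_square_test(tab)
    }
    data.frame(feature = f, statistic = ht$statistic, p_value = ht$p_value,
               method = ht$method, n_low = sum(g == levels(g)[1L]),
               n_high = sum(g == levels(g)[2L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature = character(), statistic = numeric(),
                                      p_value = numeric(), method = character(),
                                      n_low = integer(), n_high = integer())
  rownames(out) <- NULL
  if (fdr && nrow(out)) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
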