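# Shared fixtures and independent oracles used across the suite.

# Small gene x sample TPM matrix with all scored genes present.
tiny_expr <- function(n_samples = 3, seed = 42, extra = character(0)) {
  set.seed(seed)
  genes <- c("GZMA", "PRF1", immunocyt::apobec3_panel(),
             immunocyt::checkpoint_panel(), "HLA-A", "HLA-B", extra)
  m <- matrix(round(runif(length(genes) * n_samples, 0, 50), 3),
              nrow = length(genes),
              dimnames = list(genes, paste0("S", seq_len(n_samples))))
  m
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Independent brute-force Mann-Whitney U (naive pair counting).
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
  u
}

# Independent textbook chi-square statistic: sum (O - E)^2 / E.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Independent unweighted GSEA walk: +1/n_hit at hits, -1/n_miss at misses.
oracle_walk <- function(genes_in_order, set) {
  hit <- genes_in_order %in% set
  step <- ifelse(hit, 1 / sum(hit), -1 / sum(!hit))
  cumsum(step)
}

# Breslow partial-likelihood score vector, coded independently of cox_fit.
# On tie-free data Efron and Breslow coincide.
oracle_cox_score <- function(beta, times, events, x) {
  x <- as.matrix(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  score <- numeric(length(beta))
  for (i in which(events == 1)) {
    at_risk <- times >= times[i]
    s0 <- sum(w[at_risk])
    s1 <- colSums(x[at_risk, , drop = FALSE] * w[at_risk])
    score <- score + x[i, ] - s1 / s0
  }
  score
}

# Two-group exponential survival data with a given true hazard ratio.
gen_exp_surv <- function(n, true_hr, censor_frac = 0.2, base = 0.05) {
  grp <- rep(0:1, length.out = n)
  rate <- base * ifelse(grp == 1, true_hr, 1)
  t_ev <- rexp(n, rate)
  t_c <- rexp(n, base * censor_frac / (1 - censor_frac))
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), group = grp)
}
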