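#' Kaplan-Meier product-limit fit
#'
#' Product-limit estimate S(t) with Greenwood standard errors, number at
#' risk per step, median survival and its 95% confidence interval from the
#' log-log transformed band. A median (or CI bound) that is never reached is
#' reported as NA and printed as "NR"; infinity is never emitted.
#'
#' @param times Follow-up times in months, non-negative.
#' @param events Event indicators (1 observed, 0 censored).
#' @return Object of class `km_fit` with `time` (distinct event times),
#'   `surv`, `se`, `n_risk`, `n_event`, `median`, `median_ci95`, `n`,
#'   `n_events`.
#' @export
km_fit <- function(times, events) {
  ok <- !is.na(times) & !is.na(events)
  times <- times[ok]; events <- events[ok]
  if (length(times) == 0L) ic_degenerate_error("Kaplan-Meier fit needs at least one subject")
  if (any(times < 0)) ic_format_error("negative follow-up time")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "log-log")
  ev <- fit$n.event > 0
  med <- stats::quantile(fit, probs = 0.5)
  structure(list(
    time = fit$time[ev], surv = fit$surv[ev],
    se = (fit$std.err * fit$surv)[ev],  # survfit std.err is on the log scale
    n_risk = fit$n.risk[ev], n_event = fit$n.event[ev],
    median = unname(med$quantile), median_ci95 = unname(c(med$lower, med$upper)),
    n = length(times), n_events = sum(events == 1)), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  nr <- function(v) if (is.na(v)) "NR" else format(v, digits = 4)
  cat(sprintf("Kaplan-Meier fit: n = %d, events = %d\n", x$n, x$n_events))
  cat(sprintf("  median survival %s months, 95%% CI (%s-%s)\n",
              nr(x$median), nr(x$median_ci95[1]), nr(x$median_ci95[2])))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve as a step function
#' @param fit A `km_fit`.
#' @param t Times at which to evaluate S(t).
#' @return Survival probabilities.
#' @export
km_surv_at <- function(fit, t) {
  vapply(t, function(tt) {
    idx <- which(fit$time <= tt)
    if (length(idx) == 0L) 1 else fit$surv[max(idx)]
  }, numeric(1))
}

#' Restricted mean survival time from a KM curve
#' @param fit A `km_fit`.
#' @param tau Horizon (months); the curve is integrated on [0, tau].
#' @return Restricted mean in months.
#' @export
km_rmst <- function(fit, tau) {
  knots <- c(0, fit$time[fit$time < tau], tau)
  s <- c(1, fit$surv[fit$time < tau])
  sum(s * diff(knots))
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over event times; p-value from the chi-square distribution with k-1
#' degrees of freedom for k groups.
#'
#' @param times,events Follow-up times and event indicators.
#' @param group Group labels (2 or more non-empty levels).
#' @return `ic_test` with `statistic`, `p_value`, `df`, `n_per_group`.
#' @export
log_rank <- function(times, events, group) {
  group <- factor(group)
  ok <- !is.na(times) & !is.na(events) & !is.na(group)
  times <- times[ok]; events <- events[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2L)
    ic_degenerate_error("log-rank test needs at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 df = df, method = "log_rank",
                 n_per_group = as.integer(sd$n)), class = "ic_test")
}

#' Cox proportional hazards fit
#'
#' Maximizes the partial likelihood (Efron tie correction by default) and
#' reports per-covariate log hazard coefficients, hazard ratios, Wald 95%
#' confidence intervals and p-values. Constant or linearly dependent
#' covariates raise a singularity error; a monotone likelihood (complete
#' separation, infinite coefficient) is flagged as non-converged, never
#' silent.
#'
#' @param times,events Follow-up times and event indicators.
#' @param covariates Data frame (factors allowed) or numeric matrix with
#'   named columns; rows aligned with `times`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: `coefficients` (data frame with
#'   `term`, `coef`, `hr`, `ci_low`, `ci_high`, `se`, `wald_p`), `loglik`,
#'   `n`, `n_events`, `converged`, `iterations`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  if (is.null(names(covariates)) || any(!nzchar(names(covariates))))
    ic_config_error("covariates must have names")
  ok <- stats::complete.cases(covariates) & !is.na(times) & !is.na(events)
  dat <- covariates[ok, , drop = FALSE]
  times <- times[ok]; events <- events[ok]
  if (sum(events == 1) < 1L) ic_degenerate_error("Cox fit needs at least one event")
  for (nm in names(dat)) {
    v <- dat[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      ic_stop("immunocyt_singularity_error", "covariate '%s' is constant across subjects", nm)
  }
  dat$..time <- times; dat$..event <- events
  fml <- stats::as.formula(paste("survival::Surv(..time, ..event) ~",
                                 paste(sprintf("`%s`", setdiff(names(dat), c("..time", "..event"))),
                                       collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w))) converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (anyNA(beta))
    ic_stop("immunocyt_singularity_error",
            "covariate(s) %s are linearly dependent with the rest of the design",
            paste(names(beta)[is.na(beta)], collapse = ", "))
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = names(beta), coef = unname(beta), hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se), ci_high = exp(unname(beta) + z * se),
                    se = se, wald_p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(coefficients = tab, loglik = fit$loglik[length(fit$loglik)],
                 n = fit$n, n_events = fit$nevent,
                 converged = converged, iterations = fit$iter,
                 ties = ties, fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_events,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  tab <- x$coefficients
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-24s HR %.3g (95%% CI %.3g-%.3g) p = %.3g\n",
                tab$term[i], tab$hr[i], tab$ci_low[i], tab$ci_high[i], tab$wald_p[i]))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$coefficients$coef, object$coefficients$term)
}

#' Univariate screen followed by a multivariate Cox model
#'
#' Fits each candidate covariate alone against the endpoint; a candidate (a
#' multi-level factor counts as one candidate) is selected when any of its
#' coefficient-level Wald p-values falls below `alpha`, and the selected set
#' is then refitted jointly. With `alpha = 1` every candidate enters the
#' joint model. If nothing is selected the univariate table is returned with
#' a NULL multivariate model and a warning.
#'
#' @param times,events Follow-up times and event indicators.
#' @param data Data frame holding candidate columns (factors should carry
#'   their reference level first, e.g. stage I, etiology none, TIL negative,
#'   score group low).
#' @param candidates Column names of `data` to screen.
#' @param alpha Selection threshold on the univariate Wald p (default 0.05).
#' @param ties Tie handling passed to [cox_fit()].
#' @return Object of class `cox_screen`: `univariate` (stacked coefficient
#'   table with a `variable` column), `selected`, `multivariate` (a
#'   `cox_fit` or NULL), `alpha`.
#' @export
univariate_screen_then_multivariate <- function(times, events, data, candidates,
                                                alpha = 0.05, ties = "efron") {
  missing_cand <- setdiff(candidates, names(data))
  if (length(missing_cand))
    ic_config_error("candidate(s) not in data: %s", paste(missing_cand, collapse = ", "))
  uni <- list(); selected <- character(0)
  for (cand in candidates) {
    fit <- cox_fit(times, events, data[cand], ties = ties)
    tab <- fit$coefficients
    tab$variable <- cand
    uni[[cand]] <- tab
    if (any(tab$wald_p < alpha)) selected <- c(selected, cand)
  }
  uni <- do.call(rbind, uni); rownames(uni) <- NULL
  multi <- NULL
  if (length(selected)) {
    multi <- cox_fit(times, events, data[selected], ties = ties)
  } else {
    warning("no candidate reached the selection threshold; multivariate model omitted",
            call. = FALSE)
  }
  structure(list(univariate = uni, selected = selected,
                 multivariate = multi, alpha = alpha), class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf("Univariate screen (alpha = %g):\n", x$alpha))
  u <- x$univariate
  for (i in seq_len(nrow(u)))
    cat(sprintf("  %-24s HR %.3g (%.3g-%.3g) p = %.3g%s\n", u$term[i], u$hr[i],
                u$ci_low[i], u$ci_high[i], u$wald_p[i],
                if (u$variable[i] %in% x$selected) " *" else ""))
  if (is.null(x$multivariate)) cat("No covariate selected; no multivariate model.\n")
  else { cat("Multivariate model:\n"); print(x$multivariate) }
  invisible(x)
}

#' Two-factor survival stratification
#'
#' Crosses two dichotomized factors (e.g. CYT group and an exhaustion-marker
#' group) into up to four strata, runs a k-group log-rank test, and fits a
#' KM curve plus restricted mean survival time per stratum. Empty strata are
#' omitted with a warning and the degrees of freedom reduced accordingly.
#'
#' @param times,events Follow-up times and event indicators.
#' @param factor_a,factor_b Two-level factors (levels `low`, `high`) on the
#'   same samples.
#' @param name_a,name_b Display names for the two factors.
#' @return Object of class `strat_fit`: `groups` (per-sample labels such as
#'   `"cyt-high/exh-low"`), `logrank`, `fits` (named `km_fit` list), `rmst`
#'   (named, common horizon `tau`), `tau`.
#' @export
two_factor_stratification <- function(times, events, factor_a, factor_b,
                                      name_a = "cyt", name_b = "exh") {
  fa <- factor(factor_a, levels = c("low", "high"))
  fb <- factor(factor_b, levels = c("low", "high"))
  ok <- !is.na(times) & !is.na(events) & !is.na(fa) & !is.na(fb)
  times <- times[ok]; events <- events[ok]; fa <- fa[ok]; fb <- fb[ok]
  lab <- factor(paste0(name_a, "-", fa, "/", name_b, "-", fb),
                levels = as.vector(outer(c("high", "low"), c("high", "low"),
                                         function(a, b) paste0(name_a, "-", a, "/", name_b, "-", b))))
  empty <- levels(lab)[tabulate(lab, nlevels(lab)) == 0L]
  if (length(empty)) {
    warning(sprintf("empty stratum(s) omitted: %s", paste(empty, collapse = ", ")),
            call. = FALSE)
    lab <- droplevels(lab)
  }
  lr <- log_rank(times, events, lab)
  fits <- lapply(levels(lab), function(g) km_fit(times[lab == g], events[lab == g]))
  names(fits) <- levels(lab)
  tau <- min(vapply(levels(lab), function(g) max(times[lab == g]), numeric(1)))
  rmst <- vapply(fits, km_rmst, numeric(1), tau = tau)
  structure(list(groups = lab, logrank = lr, fits = fits, rmst = rmst, tau = tau),
            class = "strat_fit")
}

#' @export
print.strat_fit <- function(x, ...) {
  cat(sprintf("Two-factor stratification (%d strata), log-rank p = %.3g\n",
              nlevels(x$groups), x$logrank$p_value))
  for (g in names(x$rmst))
    cat(sprintf("  %-24s n = %3d  RMST(%.3g mo) = %.4g\n", g,
                sum(x$groups == g), x$tau, x$rmst[[g]]))
  invisible(x)
}

#' Export a KM curve as a plain table
#' @param fit A `km_fit`.
#' @return Data frame with `time`, `survival`, `se`, `n_at_risk`.
#' @export
km_table <- function(fit) {
  data.frame(time = fit$time, survival = fit$surv, se = fit$se,
             n_at_risk = fit$n_risk)
}
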