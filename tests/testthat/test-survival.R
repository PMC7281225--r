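test_that("KM equals the empirical survival function without censoring", {
  f <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(f$surv, c(2 / 3, 1 / 3, 0))
  set.seed(41)
  t <- rexp(60)
  f2 <- km_fit(t, rep(1, 60))
  emp <- vapply(f2$time, function(tt) mean(t > tt), numeric(1))
  expect_equal(f2$surv, emp)
})

test_that("product-limit hand example with censoring matches", {
  f <- km_fit(c(1, 2, 3), c(1, 1, 0))
  expect_equal(km_surv_at(f, 1), 2 / 3)
  expect_equal(km_surv_at(f, 3), 1 / 3)
  # all censored: flat curve, median not reached (NA sentinel, not Inf)
  f0 <- km_fit(c(5, 8, 2), c(0, 0, 0))
  expect_equal(km_surv_at(f0, 10), 1)
  expect_true(is.na(f0$median))
  expect_false(any(is.infinite(unlist(f0[c("median", "median_ci95")]))))
  expect_error(km_fit(numeric(0), numeric(0)), class = "immunocyt_degenerate_input_error")
})

test_that("Greenwood standard errors match the textbook formula", {
  set.seed(42)
  t <- round(rexp(50, 0.1), 1)
  ev <- rbinom(50, 1, 0.7)
  f <- km_fit(t, ev)
  # hand Greenwood: var(S) = S^2 * cumsum(d / (n (n - d)))
  gw <- f$surv * sqrt(cumsum(f$n_event / (f$n_risk * (f$n_risk - f$n_event))))
  keep <- f$surv > 0
  expect_equal(f$se[keep], gw[keep], tolerance = 1e-10)
})

test_that("log-rank is null on duplicated groups and consistent at df = 1", {
  t <- c(1, 3, 5, 7, 9); ev <- c(1, 1, 0, 1, 0)
  res <- log_rank(c(t, t), c(ev, ev), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  set.seed(43)
  tt <- rexp(80); ee <- rbinom(80, 1, 0.8); gg <- rep(c("a", "b"), 40)
  r2 <- log_rank(tt, ee, gg)
  expect_equal(r2$df, 1)
  # df=1 statistic equals the squared standardized O-E from survdiff
  sd <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
  expect_equal(r2$statistic, (sd$obs[1] - sd$exp[1])^2 / sd$var[1, 1], tolerance = 1e-8)
  expect_error(log_rank(tt, ee, rep("a", 80)), class = "immunocyt_degenerate_input_error")
})

test_that("Cox fit recovers a known hazard ratio and satisfies the score equation", {
  set.seed(44)
  d <- gen_exp_surv(800, true_hr = 0.5)
  fit <- cox_fit(d$time, d$event, data.frame(group = d$group))
  expect_true(fit$converged)
  expect_gt(fit$coefficients$hr, 0.35)
  expect_lt(fit$coefficients$hr, 0.7)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
  expect_true(fit$coefficients$ci_low < fit$coefficients$hr &
                fit$coefficients$hr < fit$coefficients$ci_high)
  # independently coded partial-likelihood score vanishes at beta-hat
  sc <- oracle_cox_score(fit$coefficients$coef, d$time, d$event,
                         matrix(d$group, ncol = 1))
  expect_lt(max(abs(sc)), 1e-6)
})

test_that("Cox rejects constant and duplicated covariates; ties modes agree tie-free", {
  set.seed(45)
  t <- rexp(100); ev <- rbinom(100, 1, 0.7); x <- rnorm(100)
  expect_error(cox_fit(t, ev, data.frame(c0 = rep(1, 100))),
               class = "immunocyt_singularity_error")
  expect_error(cox_fit(t, ev, data.frame(a = x, b = x)),
               class = "immunocyt_singularity_error")
  fe <- cox_fit(t, ev, data.frame(x = x), ties = "efron")
  fb <- cox_fit(t, ev, data.frame(x = x), ties = "breslow")
  expect_equal(fe$coefficients$coef, fb$coefficients$coef, tolerance = 1e-10)
})

test_that("complete separation is flagged as non-convergence, never silent", {
  # covariate perfectly orders the events: monotone likelihood
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  ev <- rep(1, 8)
  x <- c(1, 1, 1, 1, 0, 0, 0, 0)
  fit <- cox_fit(t, ev, data.frame(x = x))
  expect_false(fit$converged)
})

test_that("Wald CI coverage of the true log-HR is near nominal", {
  set.seed(46)
  cover <- 0; nrep <- 150
  for (i in seq_len(nrep)) {
    d <- gen_exp_surv(300, true_hr = 0.5)
    fit <- cox_fit(d$time, d$event, data.frame(group = d$group))
    ci <- c(fit$coefficients$ci_low, fit$coefficients$ci_high)
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) cover <- cover + 1
  }
  expect_gt(cover / nrep, 0.90)
  expect_lt(cover / nrep, 0.99)
})

test_that("univariate screen selects factors by their best level and refits jointly", {
  set.seed(47)
  co <- generate_cohort(sim_config(n_samples = 400, seed = 47))
  frame <- build_score_frame(co$expression)
  dat <- data.frame(group = frame$cyt_group,
                    age = co$clinical$age,
                    sex = co$clinical$sex)
  scr <- suppressWarnings(univariate_screen_then_multivariate(
    co$clinical$OS_time, co$clinical$OS_event, dat, c("group", "age", "sex")))
  expect_true("group" %in% scr$selected)
  expect_true(all(scr$selected %in% c("group", "age", "sex")))
  expect_s3_class(scr$multivariate, "cox_fit")

  # alpha = 1: everything enters the joint model
  scr_all <- univariate_screen_then_multivariate(
    co$clinical$OS_time, co$clinical$OS_event, dat, c("group", "age", "sex"),
    alpha = 1)
  expect_equal(sort(scr_all$selected), c("age", "group", "sex"))

  # a factor with one significant level enters whole
  stage <- co$clinical$stage
  scr_st <- suppressWarnings(univariate_screen_then_multivariate(
    co$clinical$OS_time, co$clinical$OS_event,
    data.frame(group = frame$cyt_group, stage = stage), c("group", "stage")))
  if ("stage" %in% scr_st$selected) {
    terms <- scr_st$multivariate$coefficients$term
    expect_equal(sum(grepl("stage", terms)), nlevels(droplevels(stage)) - 1L)
  }

  # nothing significant: warning, NULL multivariate
  set.seed(48)
  noise <- data.frame(z = rnorm(400))
  expect_warning(scr0 <- univariate_screen_then_multivariate(
    co$clinical$OS_time, co$clinical$OS_event, noise, "z", alpha = 1e-6),
    "no candidate")
  expect_null(scr0$multivariate)
})

test_that("two-factor stratification reduces cleanly when factors coincide", {
  set.seed(49)
  t <- rexp(100); ev <- rbinom(100, 1, 0.8)
  g <- dichotomize_by_median(rnorm(100))
  expect_warning(st <- two_factor_stratification(t, ev, g, g), "empty stratum")
  expect_equal(nlevels(st$groups), 2)
  expect_equal(st$logrank$df, 1)
  expect_length(st$rmst, 2)
})

test_that("stratification recovers the planted best and worst prognosis cells", {
  co <- generate_cohort(sim_config(n_samples = 400, seed = 50))
  ex <- co$expression
  cyt_g <- dichotomize_by_median(cyt_score(ex))
  exh_g <- dichotomize_by_median(log_average_score(ex, exhaustion_core_panel()))
  st <- two_factor_stratification(co$clinical$OS_time, co$clinical$OS_event,
                                  cyt_g, exh_g)
  expect_equal(nlevels(st$groups), 4)
  expect_equal(names(st$rmst)[which.max(st$rmst)], "cyt-high/exh-low")
  expect_equal(names(st$rmst)[which.min(st$rmst)], "cyt-low/exh-high")
  expect_lt(st$logrank$p_value, 0.05)
})
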