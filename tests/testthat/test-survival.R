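# Kaplan-Meier, log-rank and Cox wrappers against first-principles oracles.

test_that("KM product-limit matches a hand computation and handles censoring", {
  km <- km_estimate(c(2, 4, 6), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$median, 4)
  expect_true(km$median_reached)
  expect_equal(format_median(km), "4")

  cens <- km_estimate(c(5, 8, 12), c(0, 0, 0))
  expect_false(cens$median_reached)
  expect_equal(format_median(cens), "NR")
  expect_equal(km_survival_at(cens, c(0, 20)), c(1, 1))

  mixed <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 0))
  o <- oracle_km(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(km_survival_at(mixed, o$time), o$surv)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "nonnegative")
  expect_error(km_estimate(numeric(), logical()), "no survival records")
})

test_that("without censoring the KM curve is the empirical survivor function", {
  set.seed(11)
  for (i in 1:20) {
    t <- round(rexp(30, 0.1), 1)  # rounding induces ties
    km <- km_estimate(t, rep(1, 30))
    grid <- c(0, sort(unique(t)), max(t) + 1)
    expect_equal(km_survival_at(km, grid), vapply(grid, function(g)
      mean(t > g), 0))
    expect_true(all(diff(km$surv) <= 1e-12))  # non-increasing
  }
})

test_that("log-rank: symmetry null, oracle equivalence, and power", {
  t <- c(3, 5, 8, 3, 5, 8)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(t, rep(1, 6), g)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  expect_equal(lr$df, 1)

  # n = 6 two-group fixture with censoring, against the hand tally
  t2 <- c(2, 4, 7, 3, 6, 9)
  e2 <- c(1, 0, 1, 1, 1, 0)
  lr2 <- logrank_test(t2, e2, g)
  expect_equal(lr2$chi_square, oracle_logrank2(t2, e2, g),
               tolerance = 1e-10)

  # strongly separated exponential hazards: overwhelming evidence
  set.seed(101)
  times <- c(rexp(100, 0.01), rexp(100, 0.05), rexp(100, 0.1))
  grp <- rep(c("I", "II", "III"), each = 100)
  lr3 <- logrank_test(times, rep(1, 300), grp)
  expect_equal(lr3$df, 2)
  expect_lt(lr3$p_value, 0.001)

  expect_error(logrank_test(c(1, 2), c(1, 1), c("a", "a")), "two groups")

  # with no events anywhere the statistic carries no information
  lr0 <- logrank_test(c(1, 2, 3, 4), c(0, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)
})

test_that("Cox single-covariate fit maximizes the written-out partial likelihood", {
  # n = 4 micro-example, no ties
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                  x = c(1, 0, 1, 0))
  fit <- cox_fit(d, "x")
  expect_equal(fit$coefficients$coef,
               oracle_cox_coef(d$time, d$event, d$x), tolerance = 1e-6)
  # the fitted log partial likelihood equals the oracle's at the optimum
  expect_equal(fit$log_partial_likelihood,
               oracle_cox_loglik(fit$coefficients$coef, d$time, d$event,
                                 d$x), tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))

  set.seed(21)
  d2 <- data.frame(time = rexp(40, 0.1), event = rbinom(40, 1, 0.8),
                   x = rbinom(40, 1, 0.5))
  d2$time <- round(d2$time, 3)  # keep times distinct enough
  fit2 <- cox_fit(d2, "x")
  expect_equal(fit2$coefficients$coef,
               oracle_cox_coef(d2$time, d2$event, d2$x), tolerance = 1e-6)
})

test_that("constant covariates are dropped with a warning, not estimated", {
  d <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 1, 0),
                  x = c(1, 1, 1, 1), y = c(0, 1, 0, 1))
  expect_warning(fit <- cox_fit(d, c("x", "y")), "no variation")
  expect_equal(fit$coefficients$term, "y")
  expect_equal(fit$dropped, "x")
  expect_error(suppressWarnings(cox_fit(d, "x")), "no informative")
  expect_error(cox_fit(data.frame(time = 1, event = 0, x = 1), "x"),
               "at least one event")
})

test_that("Cox recovers a known hazard ratio from the generator's PH model", {
  cfg <- cohort_config(
    n_patients = 500,
    survival = list(hr_stage_ii = 1, hr_stage_iii = 1, hr_bm_ge4 = 3.5,
                    hr_emd = 1))
  cohort <- generate_cohort(cfg, seed = 2024)
  fit <- cox_fit(as.data.frame(cohort), "bm_ge4",
                 time = "os_months", event = "os_event")
  co <- fit$coefficients
  expect_gt(co$ci_high, 3.5)
  expect_lt(co$ci_low, 3.5)
  expect_equal(co$coef, log(3.5), tolerance = 0.25)
})

test_that("univariate OS table renders counts, medians and NR", {
  cfg <- cohort_config(n_patients = 120)
  cohort <- generate_cohort(cfg, seed = 5)
  tab <- univariate_os_table(as.data.frame(cohort),
                             factors = c("sex", "bm_ge4"))
  expect_equal(unique(tab$factor), c("sex", "bm_ge4"))
  expect_equal(sum(tab$n[tab$factor == "sex"]), 120)
  expect_equal(sum(tab$pct[tab$factor == "sex"]), 100)
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(is.character(tab$median_os))

  # a curve that never reaches 0.5 prints NR
  no_event <- data.frame(os_months = c(1, 2, 3, 4),
                         os_event = 0,
                         g = c("a", "a", "b", "b"))
  tab2 <- univariate_os_table(no_event, "g")
  expect_equal(tab2$median_os, c("NR", "NR"))

  expect_error(univariate_os_table(as.data.frame(cohort), "nope"),
               "unknown grouping")
  one_level <- data.frame(os_months = 1:3, os_event = 1, g = "a")
  expect_error(univariate_os_table(one_level, "g"), "single level")
})

test_that("a null covariate rejects near the nominal 5% level", {
  set.seed(8)
  reps <- 400
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    t <- rexp(60, 0.02)
    cens <- runif(60, 0, 80)
    g <- rep(c("a", "b"), each = 30)
    p[i] <- logrank_test(pmin(t, cens), t <= cens, g)$p_value
  }
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})
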