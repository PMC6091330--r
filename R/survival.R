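#' @title Overall-survival analysis for staged cohorts
#' @description
#' Time-to-event analysis of overall survival (months from the baseline
#' PET/CT scan to death, right-censored at last follow-up):
#' Kaplan-Meier product-limit curves with medians, log-rank comparisons
#' across stage groups, and Cox proportional-hazards models for
#' multivariate prognostic factors.  Estimation is delegated to the
#' `survival` package; these wrappers fix the conventions used
#' throughout (Breslow tie handling by default, Wald confidence
#' intervals, medians reported as "NR" when the curve never reaches
#' 0.5).
#' @name survival-stats
NULL

check_survival <- function(time, event) {
  if (length(time) == 0L) stop("no survival records", call. = FALSE)
  if (length(time) != length(event)) {
    stop("time and event differ in length", call. = FALSE)
  }
  if (anyNA(time) || any(time < 0)) {
    stop("survival times must be nonnegative and non-missing",
         call. = FALSE)
  }
  event <- as.logical(event)
  if (anyNA(event)) stop("event flags must be TRUE/FALSE or 0/1",
                         call. = FALSE)
  event
}

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator over the distinct event times.  The median is
#' the smallest time at which the estimated survival drops to 0.5 or
#' below; when the curve never does (e.g. all records censored), the
#' median is "not reached" -- a distinguished state, reported as `"NR"`
#' by [format_median()], never as infinity or `NA` arithmetic.
#'
#' @param time follow-up in months.
#' @param event logical or 0/1; `TRUE`/1 = death, `FALSE`/0 = censored.
#' @return A list of class `mm_km`: `time` (distinct observed times),
#'   `surv`, `n_risk`, `n_event`, `n_censor`, `median`,
#'   `median_reached`, `n`, `n_events`.
#' @examples
#' km <- km_estimate(c(2, 4, 6), c(1, 1, 1))
#' km$surv           # 2/3, 1/3, 0
#' format_median(km) # "4"
#' @export
km_estimate <- function(time, event) {
  event <- check_survival(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- unname(stats::quantile(fit, probs = 0.5)$quantile)
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor,
         median = if (is.na(med)) NA_real_ else med,
         median_reached = !is.na(med),
         n = length(time), n_events = sum(event)),
    class = "mm_km"
  )
}

#' Survival probability at given times
#'
#' Evaluates the Kaplan-Meier step function; S(t) = 1 for t before the
#' first observed time.
#'
#' @param km an [km_estimate()] result.
#' @param t vector of times (months).
#' @return Survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "mm_km"))
  if (anyNA(t) || any(t < 0)) stop("times must be nonnegative",
                                   call. = FALSE)
  idx <- findInterval(t, km$time)
  ifelse(idx == 0L, 1, km$surv[pmax(idx, 1L)])
}

#' @rdname km_estimate
#' @param x an `mm_km` object.
#' @param digits digits for the median.
#' @export
format_median <- function(x, digits = 3) {
  stopifnot(inherits(x, "mm_km"))
  if (x$median_reached) format(x$median, digits = digits) else "NR"
}

#' @export
print.mm_km <- function(x, ...) {
  cat(sprintf(
    "Kaplan-Meier estimate: n = %d, events = %d, median OS = %s months\n",
    x$n, x$n_events, format_median(x)))
  invisible(x)
}

#' @export
plot.mm_km <- function(x, xlab = "Months", ylab = "Overall survival",
                       ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), main = "", ...)
  invisible(x)
}

#' Log-rank test across survival groups
#'
#' Standard observed-minus-expected chi-square statistic over the pooled
#' event times, with `groups - 1` degrees of freedom.
#'
#' @param time,event as in [km_estimate()].
#' @param group group labels (at least two non-empty groups).
#' @return A list of class `mm_logrank`: `chi_square`, `df`, `p_value`,
#'   `observed`, `expected` per group.
#' @export
logrank_test <- function(time, event, group) {
  event <- check_survival(time, event)
  group <- as.character(group)
  if (length(group) != length(time)) {
    stop("group labels differ in length from times", call. = FALSE)
  }
  if (anyNA(group)) stop("missing group labels", call. = FALSE)
  tab <- table(group)
  if (length(tab) < 2L) stop("log-rank needs at least two groups",
                             call. = FALSE)
  if (any(tab == 0L)) stop("empty survival group", call. = FALSE)
  if (!any(event)) {
    # no events anywhere: the test statistic carries no information
    return(structure(
      list(chi_square = 0, df = length(tab) - 1L, p_value = 1,
           observed = rep(0, length(tab)), expected = rep(0, length(tab)),
           n = as.vector(tab), groups = names(tab)),
      class = "mm_logrank"))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  structure(
    list(chi_square = unname(sd$chisq), df = df,
         p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
         observed = sd$obs, expected = sd$exp, n = sd$n,
         groups = names(tab)),
    class = "mm_logrank"
  )
}

#' @export
print.mm_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling by
#' default; Efron available) and reports per-covariate hazard ratios
#' with Wald confidence intervals and p-values.  Covariates with no
#' variation are dropped before fitting and listed in the result rather
#' than silently producing unstable estimates; factor covariates use
#' their first level as the reference (hazard ratio 1).
#'
#' @param data data frame holding the survival and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param time,event names of the survival columns.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level Wald confidence level.
#' @return A list of class `mm_cox`: `coefficients` (data frame with
#'   `term`, `coef`, `hr`, `se`, `ci_low`, `ci_high`, `p_value`),
#'   `log_partial_likelihood`, `n`, `n_events`, `dropped`, `converged`,
#'   `iterations`, and the underlying `survival::coxph` `fit`.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    ties = c("breslow", "efron"), conf_level = 0.95) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(time, event, covariates), names(data))
  if (length(missing_cols)) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ev <- check_survival(data[[time]], data[[event]])
  if (!any(ev)) stop("Cox model needs at least one event", call. = FALSE)

  constant <- vapply(covariates, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) < 2L
  }, TRUE)
  dropped <- covariates[constant]
  if (length(dropped)) {
    warning("covariate(s) with no variation dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  kept <- covariates[!constant]
  if (!length(kept)) {
    stop("no informative covariates left to fit", call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", kept), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = ties)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  coefs <- data.frame(
    term = names(beta), coef = unname(beta), hr = exp(unname(beta)),
    se = unname(se),
    ci_low = exp(unname(beta) - z * se),
    ci_high = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs,
         log_partial_likelihood = unname(fit$loglik[length(fit$loglik)]),
         n = fit$n, n_events = fit$nevent,
         dropped = dropped,
         converged = fit$iter < survival::coxph.control()$iter.max,
         iterations = fit$iter,
         ties = ties, conf_level = conf_level, fit = fit),
    class = "mm_cox"
  )
}

#' @export
print.mm_cox <- function(x, ...) {
  cat(sprintf(
    "Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
    x$ties, x$n, x$n_events))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (length(x$dropped)) {
    cat("Dropped (no variation):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Univariate overall-survival table
#'
#' For each grouping factor, reports per-level patient counts and
#' percentages, the Kaplan-Meier median OS (`"NR"` when not reached),
#' and the log-rank p-value across the factor's levels -- the layout of
#' a clinical univariate-analysis table.
#'
#' @param cohort data frame with survival columns.
#' @param factors character vector of grouping column names; each must
#'   have at least two observed levels.
#' @param time,event names of the survival columns.
#' @return A data frame with columns `factor`, `level`, `n`, `pct`,
#'   `median_os`, `p_value` (p repeated on its factor's rows).
#' @export
univariate_os_table <- function(cohort, factors, time = "os_months",
                                event = "os_event") {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(c(time, event), names(cohort))
  if (length(missing_cols)) {
    stop("cohort lacks survival column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (f in factors) {
    if (!f %in% names(cohort)) {
      stop("unknown grouping column '", f, "'", call. = FALSE)
    }
    g <- as.character(cohort[[f]])
    levs <- sort(unique(g))
    if (length(levs) < 2L) {
      stop("grouping column '", f, "' has a single level", call. = FALSE)
    }
    lr <- logrank_test(cohort[[time]], cohort[[event]], g)
    rows <- lapply(levs, function(lv) {
      sel <- g == lv
      km <- km_estimate(cohort[[time]][sel], cohort[[event]][sel])
      data.frame(factor = f, level = lv, n = sum(sel),
                 pct = 100 * mean(sel), median_os = format_median(km),
                 p_value = lr$p_value, stringsAsFactors = FALSE)
    })
    out[[f]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
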