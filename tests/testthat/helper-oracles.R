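# Independent oracles used across the suite.  Each recomputes its
# statistic from first principles (explicit loops over the defining
# formula), deliberately sharing no code with the package functions it
# checks.

# Weighted kappa, termwise from the definition.
oracle_kappa <- function(ct, w) {
  ct <- unclass(ct)
  n <- sum(ct)
  k <- nrow(ct)
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      po <- po + w[i, j] * ct[i, j] / n
      pe <- pe + w[i, j] * (sum(ct[i, ]) / n) * (sum(ct[, j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

# Two-group log-rank chi-square: observed-minus-expected tally at each
# pooled event time, hypergeometric variance.
oracle_logrank2 <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1]
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n_tot
    if (n_tot > 1) {
      v <- v + d * (n1 / n_tot) * (1 - n1 / n_tot) *
        (n_tot - d) / (n_tot - 1)
    }
  }
  (o1 - e1)^2 / v
}

# Cox partial log-likelihood for a single covariate, written out, and
# its grid/1-D maximizer.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_coef <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(oracle_cox_loglik, interval, time = time, event = event,
                  x = x, maximum = TRUE, tol = 1e-9)$maximum
}

# Kaplan-Meier product-limit by direct multiplication.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (k in seq_along(ts)) {
    n_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(time = ts, surv = surv)
}

# Independent evaluation of the DSS stage-I / stage-III clause sets
# (rewritten from the published criteria, not via the engine).
oracle_dss_stage <- function(hb, ca, xray, igg, creat) {
  i <- hb > 10 && ca <= 10.5 && xray == "normal_or_solitary" &&
    (is.na(igg) || igg < 5)
  iii <- hb < 8.5 || ca > 12 || xray == "advanced_lytic" ||
    (!is.na(igg) && igg > 7)
  if (iii) "III" else if (i) "I" else "II"
}

random_crosstab <- function(max_total = 50) {
  n <- sample(3:max_total, 1)
  idx <- sample(9, n, replace = TRUE,
                prob = stats::runif(9))
  m <- matrix(tabulate(idx, 9), 3, 3, dimnames = list(c("I", "II", "III"),
                                                      c("I", "II", "III")))
  m
}
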