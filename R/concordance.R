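#' @title Between-system staging concordance
#' @description
#' Agreement between two three-stage classifications of the same
#' patients: 3x3 cross-tabulation, percent agreement, up/downstaging
#' summaries, and weighted Cohen's kappa.  Kappa is chance-corrected
#' agreement, \deqn{\kappa = (P_o - P_e) / (1 - P_e)} where the observed
#' and expected agreement are weighted sums over cells, 0 meaning
#' agreement no better than chance and 1 complete agreement.
#' @name concordance
NULL

#' Cross-tabulate two stage classifications
#'
#' @param stages_a,stages_b equal-length character vectors of collapsed
#'   stage labels over `"I"/"II"/"III"` (use [collapse_stage()] to strip
#'   A/B suffixes first); `stages_a` indexes rows, `stages_b` columns.
#' @param a_name,b_name display names for the two systems.
#' @return A `mm_crosstab`: a 3x3 integer matrix with stage dimnames and
#'   attributes `a_name`, `b_name`.
#' @examples
#' cohort <- fixture_table2()
#' build_crosstab(collapse_stage(cohort$stage_dsplus),
#'                collapse_stage(cohort$stage_dss), "DS Plus", "DSS")
#' @export
build_crosstab <- function(stages_a, stages_b,
                           a_name = "A", b_name = "B") {
  stages_a <- as.character(stages_a)
  stages_b <- as.character(stages_b)
  if (length(stages_a) != length(stages_b)) {
    stop("stage vectors differ in length", call. = FALSE)
  }
  bad <- setdiff(c(stages_a, stages_b), STAGES)
  if (length(bad)) {
    stop("stage labels outside I/II/III: ", paste(bad, collapse = ", "),
         "; collapse subgroup suffixes with collapse_stage() first",
         call. = FALSE)
  }
  ct <- table(factor(stages_a, levels = STAGES),
              factor(stages_b, levels = STAGES))
  m <- matrix(as.integer(ct), 3, 3,
              dimnames = list(STAGES, STAGES))
  structure(m, a_name = a_name, b_name = b_name,
            class = c("mm_crosstab", class(m)))
}

#' @export
print.mm_crosstab <- function(x, ...) {
  cat(sprintf("Cross-tabulation: %s (rows) x %s (columns), n = %d\n",
              attr(x, "a_name"), attr(x, "b_name"), sum(x)))
  print(unclass(x))
  invisible(x)
}

check_crosstab <- function(ct) {
  stopifnot(is.matrix(ct), nrow(ct) == ncol(ct))
  if (any(ct < 0)) stop("cross-tab has negative cells", call. = FALSE)
  if (sum(ct) == 0) stop("cross-tab is empty", call. = FALSE)
  invisible(TRUE)
}

#' Percent agreement of a cross-tabulation
#'
#' @param ct a square contingency table from [build_crosstab()].
#' @return `100 * trace / total`, in percent.
#' @export
percent_agreement <- function(ct) {
  check_crosstab(ct)
  100 * sum(diag(ct)) / sum(ct)
}

#' Up/downstaging summary of one system against another
#'
#' For each reference (column) stage, counts how many patients the row
#' system placed lower (downstaged), the same, or higher (upstaged), with
#' percentages of the reference-stage denominator.
#'
#' @param ct a `mm_crosstab` (rows = system A, columns = reference B).
#' @return A data frame with one row per reference stage plus an overall
#'   row: `n`, `downstaged`, `same`, `upstaged` and the matching
#'   percentage columns (percentages `NA` for empty reference stages).
#' @export
shift_summary <- function(ct) {
  check_crosstab(ct)
  k <- ncol(ct)
  rows <- lapply(seq_len(k), function(j) {
    n <- sum(ct[, j])
    down <- if (j > 1) sum(ct[seq_len(j - 1), j]) else 0L
    up <- if (j < k) sum(ct[(j + 1):k, j]) else 0L
    data.frame(reference_stage = colnames(ct)[j], n = n,
               downstaged = down, same = ct[j, j], upstaged = up,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    reference_stage = "overall", n = sum(ct),
    downstaged = sum(out$downstaged), same = sum(out$same),
    upstaged = sum(out$upstaged), stringsAsFactors = FALSE))
  for (col in c("downstaged", "same", "upstaged")) {
    out[[paste0("pct_", col)]] <-
      ifelse(out$n > 0, 100 * out[[col]] / out$n, NA_real_)
  }
  out
}

kappa_weight_matrix <- function(k, weights = c("linear", "quadratic",
                                               "unweighted")) {
  weights <- match.arg(weights)
  i <- row(diag(k)); j <- col(diag(k))
  switch(weights,
         linear = 1 - abs(i - j) / (k - 1),
         quadratic = 1 - ((i - j) / (k - 1))^2,
         unweighted = (i == j) * 1)
}

#' Weighted Cohen's kappa for a stage cross-tabulation
#'
#' Computes chance-corrected agreement with distance-based disagreement
#' weights.  With linear weights on k ordered categories,
#' \eqn{w_{ij} = 1 - |i-j|/(k-1)}, observed weighted agreement
#' \eqn{P_o = \sum w_{ij} p_{ij}}, expected
#' \eqn{P_e = \sum w_{ij} r_i c_j} from the marginals, and
#' \eqn{\kappa = (P_o-P_e)/(1-P_e)}.  The large-sample standard error
#' follows the classical weighted-kappa asymptotics (Fleiss, Cohen &
#' Everitt), giving a normal 95% confidence interval and a two-sided
#' p-value for the null of chance agreement (which uses the SE computed
#' under \eqn{\kappa = 0}).
#'
#' @param ct a square contingency table ([build_crosstab()]).
#' @param weights `"linear"` (default), `"quadratic"`, or
#'   `"unweighted"`.
#' @param conf_level confidence level for the interval.
#' @return A `kappa_result` list: `kappa`, `po`, `pe`, `weight_matrix`,
#'   `se`, `se0`, `ci_low`, `ci_high`, `p_value`, `n`, `weights`.
#' @examples
#' cohort <- fixture_table2()
#' ct <- build_crosstab(collapse_stage(cohort$stage_dsplus),
#'                      collapse_stage(cohort$stage_riss))
#' weighted_kappa(ct)
#' @export
weighted_kappa <- function(ct, weights = c("linear", "quadratic",
                                           "unweighted"),
                           conf_level = 0.95) {
  check_crosstab(ct)
  weights <- match.arg(weights)
  k <- ncol(ct)
  n <- sum(ct)
  w <- kappa_weight_matrix(k, weights)
  p <- unclass(ct) / n
  r <- rowSums(p); cl <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, cl))
  if (1 - pe < .Machine$double.eps^0.5) {
    stop("expected weighted agreement is 1 (degenerate marginals); ",
         "kappa is undefined for this table", call. = FALSE)
  }
  kap <- (po - pe) / (1 - pe)

  # row/column weighted marginal means
  wbar_i <- as.vector(w %*% cl)   # \bar w_{i.}
  wbar_j <- as.vector(r %*% w)    # \bar w_{.j}
  wsum <- outer(wbar_i, wbar_j, `+`)
  var_k <- (sum(p * (w - wsum * (1 - kap))^2) -
              (kap - pe * (1 - kap))^2) / (n * (1 - pe)^2)
  var_0 <- (sum(outer(r, cl) * (w - wsum)^2) - pe^2) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  se0 <- sqrt(max(var_0, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_value <- if (se0 > 0) {
    2 * stats::pnorm(-abs(kap) / se0)
  } else {
    NA_real_
  }
  structure(
    list(kappa = kap, po = po, pe = pe, weight_matrix = w,
         se = se, se0 = se0,
         ci_low = kap - z * se, ci_high = kap + z * se,
         conf_level = conf_level, p_value = p_value,
         n = n, weights = weights),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Weighted kappa (%s weights, n = %d): %.*f (%.0f%% CI %.*f to %.*f), p = %.3g\n",
    x$weights, x$n, digits, x$kappa, 100 * x$conf_level,
    digits, x$ci_low, digits, x$ci_high, x$p_value))
  cat(sprintf("  observed weighted agreement Po = %.4f, expected Pe = %.4f\n",
              x$po, x$pe))
  invisible(x)
}

#' One-call concordance report for two stage columns of a cohort
#'
#' Convenience wrapper chaining [build_crosstab()],
#' [percent_agreement()], [shift_summary()] and [weighted_kappa()].
#'
#' @param cohort a cohort data frame ([read_cohort()],
#'   [fixture_table2()], [generate_cohort()]).
#' @param col_a,col_b names of the two stage-label columns.
#' @param weights passed to [weighted_kappa()].
#' @return A list of class `concordance_report` with elements
#'   `crosstab`, `percent_agreement`, `shift`, `kappa`.
#' @export
concordance_report <- function(cohort, col_a, col_b, weights = "linear") {
  for (col in c(col_a, col_b)) {
    if (!col %in% names(cohort)) {
      stop("cohort has no column '", col, "'", call. = FALSE)
    }
  }
  ct <- build_crosstab(collapse_stage(cohort[[col_a]]),
                       collapse_stage(cohort[[col_b]]),
                       a_name = col_a, b_name = col_b)
  structure(
    list(crosstab = ct,
         percent_agreement = percent_agreement(ct),
         shift = shift_summary(ct),
         kappa = weighted_kappa(ct, weights = weights)),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  print(x$crosstab)
  cat(sprintf("Percent agreement: %.2f%%\n", x$percent_agreement))
  print(x$kappa)
  cat("Stage shifts (rows of the reference system):\n")
  print(x$shift, row.names = FALSE, digits = 4)
  invisible(x)
}
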