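# p-value floor used for display, mirroring R's conventional printing limit
P_FLOOR <- 2.2e-16

#' Build a test-result record
#'
#' Container shared by all hypothesis tests in the package.  Carries the raw
#' statistic, a numeric p-value, its natural-log counterpart (useful when the
#' p-value underflows double precision), a display string with the
#' `< 2.2e-16` floor, and the sidedness/method labels.
#'
#' @param statistic test statistic.
#' @param p_value numeric p-value in `[0, 1]` (may underflow to 0).
#' @param log_p natural log of the p-value, computed without underflow.
#' @param sidedness one of `"one_sided_greater"`, `"one_sided_less"`,
#'   `"two_sided"`.
#' @param method human-readable method label.
#' @return an object of class `pf_test` (a list).
#' @export
test_result <- function(statistic, p_value, log_p, sidedness, method) {
  stopifnot(sidedness %in% c("one_sided_greater", "one_sided_less", "two_sided"))
  p_value <- min(max(p_value, 0), 1)
  structure(
    list(
      statistic = statistic,
      p_value   = p_value,
      log_p     = log_p,
      p_display = if (p_value < P_FLOOR) "< 2.2e-16" else format(p_value, digits = 4),
      sidedness = sidedness,
      method    = method
    ),
    class = "pf_test"
  )
}

#' @export
print.pf_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic, digits = 6),
      ", p ", if (startsWith(x$p_display, "<")) "" else "= ", x$p_display,
      " (", x$sidedness, ")\n", sep = "")
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' No continuity correction by default: the downstream uses (fractionation
#' asymmetry, exchange direction bias) involve counts in the thousands where
#' the correction is immaterial; a flag restores it.
#'
#' @param a,b,c,d the four cell counts, row-wise: `[[a, b], [c, d]]`.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return a [test_result()] with one degree of freedom.
#' @examples
#' chi_squared_2x2(20, 10, 10, 20)
#' @export
chi_squared_2x2 <- function(a, b, c, d, correct = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero marginal row or column")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) stop("degenerate table: zero expected cell")
  dev <- abs(tab - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  log_p <- stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  test_result(stat, exp(log_p), log_p, "two_sided",
              "Pearson chi-squared (1 df)")
}

#' Exact binomial test
#'
#' Exact tail sums of the binomial pmf; `one_sided_greater` sums
#' `P(X >= k)` under `Binomial(n, p0)`.
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param p0 null success probability, strictly inside (0, 1).
#' @param sidedness tail to sum; default `"one_sided_greater"`.
#' @return a [test_result()].
#' @examples
#' exact_binomial(314, 527, 0.117)  # telomere enrichment arithmetic
#' @export
exact_binomial <- function(k, n, p0, sidedness = "one_sided_greater") {
  if (!(p0 > 0 && p0 < 1)) stop("p0 must lie strictly in (0, 1)")
  if (k < 0 || k > n || n < 1) stop("require 0 <= k <= n with n >= 1")
  if (sidedness == "one_sided_greater") {
    log_p <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  } else if (sidedness == "one_sided_less") {
    log_p <- stats::pbinom(k, n, p0, lower.tail = TRUE, log.p = TRUE)
  } else {
    # two-sided by the usual small-pmf summation, as binom.test does
    p <- stats::binom.test(k, n, p0)$p.value
    log_p <- log(p)
  }
  test_result(k, exp(log_p), log_p, sidedness, "exact binomial test")
}

#' One-sided paired t test
#'
#' Tests whether `mean(x - y) > 0`.  Zero-variance differences leave the
#' statistic undefined and are an error rather than a degenerate p-value.
#'
#' @param x,y paired numeric vectors of equal length `>= 2`.
#' @return a [test_result()].
#' @export
paired_t_one_sided <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop("degenerate differences")
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  log_p <- stats::pt(unname(tt$statistic), df = length(x) - 1,
                     lower.tail = FALSE, log.p = TRUE)
  test_result(unname(tt$statistic), unname(tt$p.value), log_p,
              "one_sided_greater", "paired t-test (one-sided, mean(x - y) > 0)")
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / n`, the family-wise threshold used for association scans.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n number of tests (e.g. number of markers), `>= 1`.
#' @return the per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 4789738)
#' @export
bonferroni_threshold <- function(alpha, n) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (length(n) != 1 || n < 1 || n != round(n)) stop("n must be a positive integer")
  alpha / n
}

#' Serialize test results to a TSV-ready data frame
#'
#' @param ... named [test_result()] objects.
#' @return data.frame with columns test, statistic, p, p_display, method.
#' @export
tests_as_table <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) > 0, !is.null(names(xs)))
  data.frame(
    test      = names(xs),
    statistic = vapply(xs, function(t) t$statistic, numeric(1)),
    p         = vapply(xs, function(t) t$p_value, numeric(1)),
    p_display = vapply(xs, function(t) t$p_display, character(1)),
    method    = vapply(xs, function(t) t$method, character(1)),
    row.names = NULL
  )
}
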