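# Statistical procedures used for the group comparisons: two-sided
# Wilcoxon rank-sum, paired and one-sample t-tests, Benjamini-Hochberg
# correction, geometric mean, and the boxplot summary convention.

stat_result <- function(test, statistic, p_value, method, n, sidedness) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), method = method, n = n,
                 sidedness = sidedness),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s (%s, %s): statistic %.4g, p = %.4g, n = %s\n",
              x$test, x$sidedness, x$method, x$statistic, x$p_value,
              paste(x$n, collapse = " vs ")))
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) comparison of two independent groups with
#' midranks for ties. The p-value is exact (full enumeration of the
#' rank-sum distribution) when both groups have at most
#' `exact_threshold` observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. Two-sided exact p is twice the smaller tail, capped at 1.
#'
#' @param x,y Non-empty numeric vectors.
#' @param sidedness `"two-sided"`, `"less"` or `"greater"`.
#' @param exact_threshold Per-group size at or below which the exact
#'   distribution is used (default 10).
#' @return A `stat_result`; `statistic` is the Mann-Whitney U of `x`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              sidedness = c("two-sided", "less", "greater"),
                              exact_threshold = 10L) {
  sidedness <- match.arg(sidedness)
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  alt <- switch(sidedness, "two-sided" = "two.sided", sidedness)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= exact_threshold && length(y) <= exact_threshold &&
    !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = TRUE))
  stat_result("Wilcoxon rank-sum", wt$statistic, wt$p.value,
              if (exact) "exact" else "normal-approximation",
              c(length(x), length(y)), sidedness)
}

#' Paired two-sample t-test
#'
#' One-sample t-test on the paired differences, df = n - 1.
#'
#' @param x,y Numeric vectors of equal length (>= 2 pairs) whose
#'   differences have nonzero variance.
#' @param sidedness `"two-sided"`, `"less"` or `"greater"`.
#' @return A `stat_result`.
#' @export
paired_t_test <- function(x, y,
                          sidedness = c("two-sided", "less", "greater")) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::var(d) == 0)
    stop("zero variance of paired differences; t statistic undefined")
  alt <- switch(sidedness, "two-sided" = "two.sided", sidedness)
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alt)
  stat_result("paired t-test", tt$statistic, tt$p.value, "exact",
              length(x), sidedness)
}

#' One-sample t-test
#'
#' @param x Numeric vector (n >= 2, nonzero variance).
#' @param mu0 Null-hypothesis mean.
#' @param sidedness `"two-sided"`, `"less"` or `"greater"`.
#' @return A `stat_result`.
#' @export
one_sample_t_test <- function(x, mu0 = 0,
                              sidedness = c("two-sided", "less", "greater")) {
  sidedness <- match.arg(sidedness)
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::var(x) == 0)
    stop("zero variance; t statistic undefined")
  alt <- switch(sidedness, "two-sided" = "two.sided", sidedness)
  tt <- stats::t.test(x, mu = mu0, alternative = alt)
  stat_result("one-sample t-test", tt$statistic, tt$p.value, "exact",
              length(x), sidedness)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone non-decreasing in
#' rank, capped at 1, returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Geometric mean
#'
#' `exp(mean(log(x)))` for strictly positive values.
#'
#' @param x Numeric vector, all > 0.
#' @return The geometric mean.
#' @export
geometric_mean <- function(x) {
  if (length(x) == 0L) stop("empty input")
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

#' Boxplot summary with 1.5 IQR whiskers
#'
#' Median and quartiles by linear interpolation of order statistics;
#' whiskers extend to the most extreme data values within 1.5 times the
#' interquartile range of the box, and values beyond are reported as
#' outliers.
#'
#' @param x Numeric vector (n >= 1).
#' @return List of class `boxplot_summary`: `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
boxplot_summary <- function(x) {
  if (length(x) == 0L) stop("empty input")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(inside), whisker_high = max(inside),
                 outliers = x[x < lo_fence | x > hi_fence],
                 n = length(x)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(
    "<boxplot_summary> n = %d | whiskers [%.4g, %.4g] box [%.4g, %.4g] median %.4g | %d outlier(s)\n",
    x$n, x$whisker_low, x$whisker_high, x$q1, x$q3, x$median,
    length(x$outliers)))
  invisible(x)
}
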