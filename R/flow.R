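# Flow-FISH gating statistics: negative-control percentile gate,
# percent positive, background-corrected geometric mean, top-fraction
# sort.

#' Percentile gate from a negative control
#'
#' Threshold at the q-th percentile (linear interpolation between order
#' statistics) of a non-expressing control sample; events strictly above
#' the threshold are called positive. The conventional gate is the 99th
#' percentile of undifferentiated cells, which do not express Xist.
#'
#' @param control A [flow_sample()].
#' @param q Percentile in `[0, 100]` (default 99).
#' @return The gate threshold (intensity).
#' @export
percentile_gate <- function(control, q = 99) {
  stopifnot(inherits(control, "flow_sample"), q >= 0, q <= 100)
  stats::quantile(control$events, q / 100, type = 7, names = FALSE)
}

#' Percent of events above a gate
#'
#' @param sample A [flow_sample()].
#' @param threshold Gate threshold; positivity is strict (`>`).
#' @return Percent positive in `[0, 100]`.
#' @export
percent_positive <- function(sample, threshold) {
  stopifnot(inherits(sample, "flow_sample"))
  100 * sum(sample$events > threshold) / sample$n_events
}

#' Background-corrected geometric mean of the positive fraction
#'
#' Geometric mean of the events above the gate, minus the geometric mean
#' of the control sample. Non-positive event values cannot enter a
#' geometric mean and are excluded with a warning; the corrected value
#' may be negative and is returned as-is.
#'
#' @param sample A [flow_sample()].
#' @param threshold Gate threshold.
#' @param control The control [flow_sample()] used for background
#'   correction.
#' @return List of class `gate_result`: `threshold`, `percent_positive`,
#'   `geomean_positive`, `geomean_control`, `corrected_geomean`. With no
#'   positive events the geometric means are `NA` and the result carries
#'   `flag = "no positive events"`.
#' @export
corrected_geomean <- function(sample, threshold, control) {
  stopifnot(inherits(sample, "flow_sample"),
            inherits(control, "flow_sample"))
  pos <- sample$events[sample$events > threshold]
  flag <- NULL
  if (any(pos <= 0)) {
    warning("excluding non-positive event values from geometric mean")
    pos <- pos[pos > 0]
  }
  ctrl <- control$events
  if (any(ctrl <= 0)) {
    warning("excluding non-positive control values from geometric mean")
    ctrl <- ctrl[ctrl > 0]
  }
  if (length(pos) == 0L) {
    flag <- "no positive events"
    gm_pos <- NA_real_
  } else gm_pos <- geometric_mean(pos)
  gm_ctrl <- geometric_mean(ctrl)
  corr <- gm_pos - gm_ctrl
  if (is.null(flag) && !is.na(corr) && corr < 0)
    flag <- "corrected geometric mean is negative"
  structure(list(threshold = threshold,
                 percent_positive = percent_positive(sample, threshold),
                 geomean_positive = gm_pos, geomean_control = gm_ctrl,
                 corrected_geomean = corr, flag = flag),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(
    "<gate_result> threshold %.4g | %.2f%% positive | corrected geomean %.4g\n",
    x$threshold, x$percent_positive, x$corrected_geomean))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Indices of the brightest fraction of events
#'
#' Selects the `ceiling(frac * n)` highest-intensity events, as in
#' sorting the top 15% Xist-positive cells. Ties are broken by original
#' event order.
#'
#' @param sample A [flow_sample()].
#' @param frac Fraction in `(0, 1]` (default 0.15).
#' @return Integer vector of event indices.
#' @export
top_fraction <- function(sample, frac = 0.15) {
  stopifnot(inherits(sample, "flow_sample"), frac > 0, frac <= 1)
  k <- ceiling(frac * sample$n_events)
  order(sample$events, decreasing = TRUE)[seq_len(k)]
}
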