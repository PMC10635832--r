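#' Configuration of a simulated Flow-FISH sample
#'
#' Events are log-normal autofluorescence draws; a non-control sample
#' additionally contains an expressing subpopulation whose intensities
#' are multiplied by a fold change, emulating the Xist-positive fraction
#' appearing upon differentiation.
#'
#' @param n_events Number of events (>= 1). Real acquisitions measure at
#'   least 30,000 cells per sample; the default matches that scale.
#' @param control_log_mean,control_log_sd Mean and sd of log-intensity of
#'   the autofluorescence (non-expressing) population.
#' @param expressing_fraction Fraction of events in the expressing
#'   subpopulation, in `[0, 1]`.
#' @param expressing_fold_change Multiplicative intensity shift of the
#'   expressing subpopulation (>= 1).
#' @param seed Integer seed.
#' @return A list of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 30000L,
                            control_log_mean = log(100),
                            control_log_sd = 0.5,
                            expressing_fraction = 0.1,
                            expressing_fold_change = 50,
                            seed = 1L) {
  stopifnot(n_events >= 1L,
            expressing_fraction >= 0, expressing_fraction <= 1,
            expressing_fold_change >= 1, control_log_sd > 0)
  structure(list(n_events = as.integer(n_events),
                 control_log_mean = control_log_mean,
                 control_log_sd = control_log_sd,
                 expressing_fraction = expressing_fraction,
                 expressing_fold_change = expressing_fold_change,
                 seed = as.integer(seed)),
            class = "flow_sim_config")
}

#' Flow cytometry sample
#'
#' @param events Numeric vector of per-event fluorescence intensities
#'   (finite; positive values expected for geometric-mean statistics).
#' @param label Sample label.
#' @return A list of class `flow_sample` with `events`, `label`,
#'   `n_events`.
#' @export
flow_sample <- function(events, label = "sample") {
  if (!is.numeric(events) || length(events) == 0L)
    stop("'events' must be a non-empty numeric vector")
  if (!all(is.finite(events))) stop("events must be finite")
  structure(list(events = as.numeric(events), label = label,
                 n_events = length(events)),
            class = "flow_sample")
}

#' Simulate a Flow-FISH sample
#'
#' Draws `n_events` log-normal autofluorescence intensities; unless
#' `is_control`, the first `round(expressing_fraction * n_events)` events
#' are multiplied by the fold change. Because the base draws are made
#' first, a sample with `expressing_fraction = 0` is identical to the
#' control at the same seed.
#'
#' @param config A [flow_sim_config()].
#' @param is_control If `TRUE`, no expressing subpopulation is added.
#' @return A [flow_sample()].
#' @export
generate_flow_sample <- function(config, is_control = FALSE) {
  stopifnot(inherits(config, "flow_sim_config"))
  run_seeded(config$seed, {
    ev <- stats::rlnorm(config$n_events, config$control_log_mean,
                        config$control_log_sd)
    n_pos <- if (is_control) 0L else
      round(config$expressing_fraction * config$n_events)
    if (n_pos > 0)
      ev[seq_len(n_pos)] <- ev[seq_len(n_pos)] * config$expressing_fold_change
    flow_sample(ev, label = if (is_control) "control" else "sample")
  })
}
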