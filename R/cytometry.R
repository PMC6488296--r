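#' Scalar calcium influx from an Indo-1 ratio time course
#'
#' Computes the normalized "calcium influx (a.u.)" summary: the mean Indo-1
#' ratio over the response window minus the mean over the baseline window,
#' divided by the same raw statistic computed on the internal control sample
#' (20 nM dark-ON ligand). Window endpoints are inclusive on both sides. The
#' result can be non-positive for non-responding samples; it is invariant to
#' adding a constant to the whole trace.
#'
#' @param time Time since acquisition start, seconds (stimulus is added after
#'   the baseline window).
#' @param value Indo-1 ratio values (binned means or per-event ratios).
#' @param control_raw The raw (unnormalized) response-minus-baseline
#'   statistic of the control sample; must be positive. Compute it with
#'   [calcium_influx_raw()].
#' @param baseline_window,response_window Two-element numeric windows,
#'   seconds; defaults 30-60 s and 250-400 s.
#' @return Normalized calcium influx, a.u.
#' @examples
#' t <- seq(0, 450, by = 5)
#' y <- 1 + 0.8 * plogis((t - 150) / 20)
#' ctrl <- calcium_influx_raw(t, y)
#' calcium_influx_au(t, y, control_raw = ctrl) # 1 by construction
#' @export
calcium_influx_au <- function(time, value, control_raw,
                              baseline_window = c(30, 60),
                              response_window = c(250, 400)) {
  if (!is.numeric(control_raw) || length(control_raw) != 1 || control_raw <= 0)
    stop("'control_raw' must be a single positive number")
  calcium_influx_raw(time, value, baseline_window, response_window) /
    control_raw
}

#' @describeIn calcium_influx_au The raw response-minus-baseline statistic
#'   (mean over the response window minus mean over the baseline window),
#'   used both for samples and for the normalizing control.
#' @export
calcium_influx_raw <- function(time, value, baseline_window = c(30, 60),
                               response_window = c(250, 400)) {
  stopifnot(length(time) == length(value))
  .window_mean <- function(win, name) {
    sel <- time >= win[1] & time <= win[2]
    if (!any(sel))
      stop("no events in the ", name, " window [", win[1], ", ", win[2], "] s")
    mean(value[sel])
  }
  .window_mean(response_window, "response") -
    .window_mean(baseline_window, "baseline")
}

#' Percentage of responding cells
#'
#' The responder threshold is the given percentile (default 90th, linear
#' interpolation convention) of the per-event ratios acquired during the
#' baseline window; the result is the percentage of response-window events
#' strictly above that threshold (ties count as non-responding). For a
#' sample whose response events are distributed like baseline this is ~10%
#' by construction. Invariant under any strictly monotone transform of the
#' ratio values.
#'
#' @param event_time Per-event acquisition times, seconds.
#' @param ratio Per-event Indo-1 ratios.
#' @param baseline_window,response_window Analysis windows, seconds.
#' @param percentile Baseline percentile defining the threshold (default 90).
#' @param min_events Minimum number of baseline events required.
#' @return Percentage of responding cells in \[0, 100\].
#' @export
responding_fraction <- function(event_time, ratio,
                                baseline_window = c(30, 60),
                                response_window = c(250, 400),
                                percentile = 90, min_events = 10) {
  stopifnot(length(event_time) == length(ratio))
  base <- ratio[event_time >= baseline_window[1] &
                  event_time <= baseline_window[2]]
  resp <- ratio[event_time >= response_window[1] &
                  event_time <= response_window[2]]
  if (length(base) < min_events)
    stop("too few baseline events (", length(base), " < ", min_events, ")")
  if (length(resp) == 0)
    stop("no events in the response window")
  thr <- stats::quantile(base, percentile / 100, names = FALSE, type = 7)
  100 * mean(resp > thr)
}
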