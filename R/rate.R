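#' Pipeline parameters
#'
#' Collects every tunable of the instantaneous-rate pipeline with its
#' default. See the package vignette for the rationale behind each choice.
#'
#' @param cutoff Low-pass cutoff in Hz applied to radar channels.
#' @param filter_order Butterworth order of the one-way low-pass prototype.
#' @param min_interval Minimum peak separation in seconds.
#' @param min_prominence Minimum peak prominence (signal units); `NULL` for
#'   the MAD-scaled automatic value.
#' @param quality_threshold Signal-quality index below which a rate point is
#'   discarded as abnormal. The default 0.5 accepts consecutive-interval
#'   ratios within a factor of two.
#' @param grid_rate Uniform resampling rate of the output series, Hz.
#' @param convention Frequency-assignment convention used inside the quality
#'   index: `"forward"` (rate of the interval after each peak; literal
#'   reading of the defining recursion, under which the trailing factor of
#'   the index is identically 1) or `"centered"` (two-interval average, which
#'   makes both factors informative).
#' @param interp `"linear"` (default) or `"monotone"` (monotone Hermite
#'   cubic) interpolation onto the uniform grid.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(cutoff = 3.3,
                            filter_order = 4L,
                            min_interval = 0.25,
                            min_prominence = NULL,
                            quality_threshold = 0.5,
                            grid_rate = 10,
                            convention = c("forward", "centered"),
                            interp = c("linear", "monotone")) {
  convention <- match.arg(convention)
  interp <- match.arg(interp)
  assert_scalar_num(quality_threshold, "quality_threshold", positive = TRUE)
  if (quality_threshold > 1) stop_respiradar("'quality_threshold' must be in (0, 1]")
  assert_scalar_num(grid_rate, "grid_rate", positive = TRUE)
  structure(list(cutoff = cutoff, filter_order = filter_order,
                 min_interval = min_interval, min_prominence = min_prominence,
                 quality_threshold = quality_threshold, grid_rate = grid_rate,
                 convention = convention, interp = interp),
            class = "pipeline_params")
}

#' Instantaneous respiration frequency from peak intervals
#'
#' The instantaneous frequency is the reciprocal of the interval between
#' consecutive breath peaks. Under the `"forward"` convention the frequency
#' of the interval \eqn{[t_l, t_{l+1}]} is assigned to \eqn{t_l}; under
#' `"centered"` interior peaks get the two-interval average
#' \eqn{2 / (t_{m+1} - t_{m-1})}.
#'
#' @param peaks A `peak_series` with at least two peaks.
#' @param convention `"forward"` or `"centered"`.
#' @return List with `times` (s) and `freq` (Hz).
#' @export
instantaneous_frequency <- function(peaks, convention = c("forward", "centered")) {
  convention <- match.arg(convention)
  t <- peaks$times
  if (length(t) < 2L) stop_respiradar("insufficient peaks")
  if (any(diff(t) <= 0)) stop_respiradar("zero interval")
  if (convention == "forward") {
    list(times = t[-length(t)], freq = 1 / diff(t))
  } else {
    if (length(t) < 3L) stop_respiradar("insufficient peaks")
    n <- length(t)
    list(times = t[2:(n - 1)], freq = 2 / (t[3:n] - t[1:(n - 2)]))
  }
}

#' Per-peak signal-quality index
#'
#' Scores the consistency of the two intervals around each interior peak.
#' With \eqn{f_m} the instantaneous frequency at peak \eqn{t_m} (under the
#' chosen convention), the backward and forward interval--frequency products
#' \deqn{\alpha = (t_m - t_{m-1})\, f_m, \qquad \beta = (t_{m+1} - t_m)\, f_m}
#' are both 1 for perfectly regular breathing, and the index
#' \deqn{Q(t_m) = \exp\{-(|\ln\alpha| + |\ln\beta|)\} \in (0, 1]}
#' decays symmetrically as either interval deviates. First and last peaks
#' lack a neighbour and carry no quality value.
#'
#' @param peaks A `peak_series` with at least three peaks.
#' @param convention Frequency convention, as in [instantaneous_frequency()].
#' @return List with `times` (interior peak times) and `quality` in (0, 1].
#' @export
quality_metric <- function(peaks, convention = c("forward", "centered")) {
  convention <- match.arg(convention)
  t <- peaks$times
  if (length(t) < 3L) stop_respiradar("insufficient peaks")
  if (any(diff(t) <= 0)) stop_respiradar("zero interval")
  n <- length(t)
  m <- 2:(n - 1)
  f_m <- switch(convention,
    forward = 1 / (t[m + 1] - t[m]),
    centered = 2 / (t[m + 1] - t[m - 1]))
  alpha <- (t[m] - t[m - 1]) * f_m
  beta <- (t[m + 1] - t[m]) * f_m
  list(times = t[m], quality = exp(-(abs(log(alpha)) + abs(log(beta)))))
}

#' Remove low-quality (abnormal) rate points
#'
#' Retains exactly the points whose quality reaches the threshold. Double
#' detections and missed breaths produce interval outliers whose quality
#' falls well below 1; thresholding drops them before interpolation.
#'
#' @param times Event times (s).
#' @param freq Instantaneous frequency at the events (Hz).
#' @param quality Quality index at the events.
#' @param threshold Retention threshold in (0, 1].
#' @return List with filtered `times`, `freq`, `quality`. Emits a warning if
#'   fewer than two points survive (an empty result is a contract state, not
#'   an error).
#' @export
remove_abnormal <- function(times, freq, quality, threshold = 0.5) {
  stopifnot(length(times) == length(freq), length(times) == length(quality))
  assert_scalar_num(threshold, "threshold", positive = TRUE)
  if (threshold > 1) stop_respiradar("'threshold' must be in (0, 1]")
  keep <- quality >= threshold
  out <- list(times = times[keep], freq = freq[keep], quality = quality[keep])
  if (sum(keep) < 2L)
    warning("fewer than 2 rate points survive quality gating", call. = FALSE)
  out
}

#' Resample an event series onto a uniform grid
#'
#' Interpolates frequency and quality from breath-event times onto a uniform
#' grid spanning the events (no extrapolation beyond the data span); the
#' interpolant passes through the input points.
#'
#' @param times Event times (s), at least two.
#' @param freq Frequency at the events (Hz).
#' @param quality Quality at the events.
#' @param grid_rate Grid rate in Hz.
#' @param interp `"linear"` or `"monotone"`.
#' @return List with `grid_times`, `freq_interp`, `quality_interp`, `bpm`
#'   (`60 * freq_interp`).
#' @export
interpolate_uniform <- function(times, freq, quality, grid_rate = 10,
                                interp = c("linear", "monotone")) {
  interp <- match.arg(interp)
  if (length(times) < 2L) stop_respiradar("insufficient data for interpolation")
  stopifnot(length(times) == length(freq), length(times) == length(quality))
  grid <- seq(times[1], times[length(times)], by = 1 / grid_rate)
  fi <- interp_fun(times, freq, interp)(grid)
  qi <- interp_fun(times, quality, interp)(grid)
  list(grid_times = grid, freq_interp = fi, quality_interp = qi,
       bpm = to_bpm(fi))
}

interp_fun <- function(x, y, interp) {
  if (interp == "linear") function(g) stats::approx(x, y, xout = g)$y
  else stats::splinefun(x, y, method = "monoH.FC")
}

#' Convert frequency in Hz to breaths per minute
#' @param freq Frequency in Hz (non-negative).
#' @return `60 * freq`.
#' @export
to_bpm <- function(freq) {
  if (any(freq < 0, na.rm = TRUE)) stop_respiradar("negative frequency")
  60 * freq
}

#' Estimate the instantaneous respiratory-rate series of a channel
#'
#' Runs the full pipeline on one channel: low-pass filtering (radar channels
#' only; the displacement reference bypasses it), peak detection,
#' peak-interval instantaneous frequency, quality scoring, abnormal-point
#' removal, and uniform resampling to a breaths-per-minute series.
#'
#' @param signal A [channel_signal()].
#' @param params A [pipeline_params()].
#' @return An object of class `inst_rate` carrying all intermediate series:
#'   `peaks`, event-level `event_times` / `freq` / `quality`, the retained
#'   events after gating, and the uniform-grid `grid_times` / `freq_interp` /
#'   `quality_interp` / `bpm`.
#' @examples
#' rec <- simulate_recording(resp_scenario(c(30, 60)))
#' fit <- analyze_channel(as_channel(rec$iq, "I"))
#' summary(fit)
#' @export
analyze_channel <- function(signal, params = pipeline_params()) {
  if (!inherits(signal, "channel_signal")) stop_respiradar("not a channel_signal")
  if (!inherits(params, "pipeline_params")) stop_respiradar("not pipeline_params")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_respiradar("stage %s: %s", name, conditionMessage(e)))
  }
  filtered <- if (signal$kind == "R") signal else
    stage("lowpass", lowpass_respiration(signal, params$cutoff, params$filter_order))
  peaks <- stage("peaks",
    detect_peaks(filtered, params$min_interval, params$min_prominence))
  instf <- stage("instfreq", instantaneous_frequency(peaks, params$convention))
  qual <- stage("quality", quality_metric(peaks, params$convention))
  # align frequency with quality on the interior peaks
  ev_t <- qual$times
  ev_f <- instf$freq[match(ev_t, instf$times)]
  if (params$convention == "forward" && anyNA(ev_f))
    stop_respiradar("stage align: event times mismatch")
  gated <- stage("remove_abnormal",
    remove_abnormal(ev_t, ev_f, qual$quality, params$quality_threshold))
  grid <- stage("interpolate",
    interpolate_uniform(gated$times, gated$freq, gated$quality,
                        params$grid_rate, params$interp))
  structure(list(
    kind = signal$kind,
    params = params,
    peaks = peaks,
    event_times = ev_t, freq = ev_f, quality = qual$quality,
    retained_times = gated$times, retained_freq = gated$freq,
    retained_quality = gated$quality,
    n_removed = length(ev_t) - length(gated$times),
    grid_times = grid$grid_times,
    freq_interp = grid$freq_interp,
    quality_interp = grid$quality_interp,
    bpm = grid$bpm
  ), class = "inst_rate")
}

#' Choose between the I- and Q-derived rate series
#'
#' The residual phase of the front end sets the operating point of the two
#' quadrature channels; near a null, one channel's respiratory fundamental
#' collapses (its content doubles in frequency) while the other is maximal.
#' The series with the higher mean event quality is returned; on an exact
#' tie the Q-derived series wins.
#'
#' @param i_series,q_series `inst_rate` objects from the I and Q channels of
#'   the same recording.
#' @return One of the two inputs.
#' @export
select_channel <- function(i_series, q_series) {
  stopifnot(inherits(i_series, "inst_rate"), inherits(q_series, "inst_rate"))
  mq <- function(s) if (length(s$quality)) mean(s$quality) else -Inf
  if (mq(i_series) > mq(q_series)) i_series else q_series
}

#' Analyze a simulated or loaded recording
#'
#' Convenience wrapper running [analyze_channel()] on the requested channel
#' of a recording; `channel = "auto"` analyzes both radar channels and keeps
#' the one selected by [select_channel()].
#'
#' @param recording List with elements `iq` (`iq_trace`) and/or `reference`
#'   (`ref_trace`), as returned by [simulate_recording()] or
#'   [read_recording()].
#' @param params A [pipeline_params()].
#' @param channel `"auto"`, `"I"`, `"Q"`, or `"R"`.
#' @return An `inst_rate`.
#' @export
analyze_recording <- function(recording, params = pipeline_params(),
                              channel = c("auto", "I", "Q", "R")) {
  channel <- match.arg(channel)
  if (channel == "R") {
    if (is.null(recording$reference)) stop_respiradar("recording has no reference trace")
    return(analyze_channel(as_channel(recording$reference), params))
  }
  if (is.null(recording$iq)) stop_respiradar("recording has no I/Q trace")
  if (channel == "auto") {
    select_channel(analyze_channel(as_channel(recording$iq, "I"), params),
                   analyze_channel(as_channel(recording$iq, "Q"), params))
  } else {
    analyze_channel(as_channel(recording$iq, channel), params)
  }
}

#' @export
print.inst_rate <- function(x, ...) {
  cat(sprintf("Instantaneous respiratory rate (%s channel, %s convention)\n",
              x$kind, x$params$convention))
  cat(sprintf("  %d peaks, %d events, %d removed by quality < %.2f\n",
              length(x$peaks$times), length(x$event_times), x$n_removed,
              x$params$quality_threshold))
  cat(sprintf("  grid: %d points @ %g Hz; mean %.1f bpm (sd %.2f)\n",
              length(x$grid_times), x$params$grid_rate,
              mean(x$bpm), stats::sd(x$bpm)))
  invisible(x)
}

#' @export
summary.inst_rate <- function(object, ...) {
  out <- list(
    kind = object$kind,
    convention = object$params$convention,
    n_peaks = length(object$peaks$times),
    n_events = length(object$event_times),
    n_removed = object$n_removed,
    mean_quality = if (length(object$quality)) mean(object$quality) else NA_real_,
    mean_bpm = mean(object$bpm),
    median_bpm = stats::median(object$bpm),
    sd_bpm = stats::sd(object$bpm),
    range_bpm = range(object$bpm)
  )
  class(out) <- "summary.inst_rate"
  out
}

#' @export
print.summary.inst_rate <- function(x, ...) {
  cat(sprintf("Respiratory rate summary (%s channel)\n", x$kind))
  cat(sprintf("  peaks %d | events %d | removed %d | mean quality %.3f\n",
              x$n_peaks, x$n_events, x$n_removed, x$mean_quality))
  cat(sprintf("  bpm: mean %.2f, median %.2f, sd %.2f, range [%.1f, %.1f]\n",
              x$mean_bpm, x$median_bpm, x$sd_bpm,
              x$range_bpm[1], x$range_bpm[2]))
  invisible(x)
}

#' Plot an instantaneous-rate series
#'
#' Breaths-per-minute trace on the uniform grid with the retained breath
#' events overlaid; the lower panel shows the interpolated quality index.
#'
#' @param x An `inst_rate`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.inst_rate <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$grid_times, x$bpm, type = "l",
                 xlab = "time [s]", ylab = "rate [bpm]",
                 main = sprintf("Instantaneous respiratory rate (%s)", x$kind), ...)
  graphics::points(x$retained_times, to_bpm(x$retained_freq), pch = 20,
                   col = "grey40", cex = 0.5)
  graphics::plot(x$grid_times, x$quality_interp, type = "l",
                 xlab = "time [s]", ylab = "quality", ylim = c(0, 1))
  graphics::abline(h = x$params$quality_threshold, lty = 2)
  invisible(x)
}
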