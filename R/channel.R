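#' Single-channel signal container
#'
#' A uniformly sampled scalar signal entering the rate pipeline: one of the
#' radar baseband channels (`"I"`, `"Q"`) or the displacement reference
#' (`"R"`). The kind matters downstream: radar channels are low-pass
#' filtered to isolate the respiration band, the reference is not.
#'
#' @param times Sample times in seconds, uniform grid.
#' @param values Signal values (a.u. for I/Q, metres for R).
#' @param kind One of `"I"`, `"Q"`, `"R"`.
#' @return An object of class `channel_signal`.
#' @export
channel_signal <- function(times, values, kind = c("I", "Q", "R")) {
  kind <- match.arg(kind)
  if (length(times) != length(values))
    stop_respiradar("times and values lengths differ")
  if (length(times) < 2L) stop_respiradar("signal too short")
  if (!is_uniform_grid(times, tol = 1e-6))
    stop_respiradar("non-uniform time grid")
  if (any(!is.finite(values))) stop_respiradar("non-finite signal values")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind),
            sampling_rate = 1 / stats::median(diff(times)),
            class = "channel_signal")
}

#' Extract a pipeline channel from a simulated or recorded trace
#'
#' @param x An `iq_trace` or `ref_trace`.
#' @param kind `"I"` or `"Q"` for an `iq_trace`; ignored for a `ref_trace`
#'   (always `"R"`).
#' @return A [channel_signal()].
#' @export
as_channel <- function(x, kind = "I") {
  if (inherits(x, "iq_trace")) {
    kind <- match.arg(kind, c("I", "Q"))
    channel_signal(x$times, if (kind == "I") x$i else x$q, kind)
  } else if (inherits(x, "ref_trace")) {
    channel_signal(x$times, x$displacement, "R")
  } else stop_respiradar("cannot extract a channel from class '%s'", class(x)[1])
}

#' @export
print.channel_signal <- function(x, ...) {
  cat(sprintf("Channel %s: %d samples @ %.4g Hz (%.1f s)\n",
              x$kind, length(x$times), attr(x, "sampling_rate"),
              x$times[length(x$times)] - x$times[1]))
  invisible(x)
}

#' Zero-phase low-pass filter isolating the respiration band
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (zero net group delay, so breath-peak times are not shifted) to a radar
#' channel. The default 3.3 Hz cutoff passes respiratory fundamentals of
#' small rodents (up to ~200 bpm) while rejecting cardiac and wideband noise
#' components. The displacement reference must bypass this stage.
#'
#' @param signal A [channel_signal()] of kind `"I"` or `"Q"`.
#' @param cutoff Cutoff frequency in Hz.
#' @param order Butterworth order of the one-way prototype (applied twice).
#' @return A filtered [channel_signal()] of the same kind.
#' @export
lowpass_respiration <- function(signal, cutoff = 3.3, order = 4L) {
  if (!inherits(signal, "channel_signal")) stop_respiradar("not a channel_signal")
  if (signal$kind == "R") stop_respiradar("reference must bypass LPF")
  fs <- attr(signal, "sampling_rate")
  assert_scalar_num(cutoff, "cutoff", positive = TRUE)
  if (fs <= 2 * cutoff)
    stop_respiradar("sampling rate (%g Hz) must exceed twice the cutoff (%g Hz)",
                    fs, cutoff)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtered <- signal::filtfilt(bf, signal$values)
  channel_signal(signal$times, filtered, signal$kind)
}

#' Detect breath peaks in a filtered channel
#'
#' Finds strict local maxima, keeps those whose topographic prominence
#' reaches `min_prominence`, then enforces a minimum peak separation by
#' discarding, from the smallest peaks up, any peak closer than
#' `min_interval` to a larger retained one.
#'
#' Defaults: `min_interval = 0.25` s caps the detectable rate at 240 bpm,
#' above any anesthetized-rodent respiratory rate; `min_prominence = NULL`
#' auto-selects 0.3 times the robust (MAD-based) standard deviation of the
#' signal, scaling the threshold to the breathing-band amplitude.
#'
#' @param signal A [channel_signal()] (filtered radar channel, or reference).
#' @param min_interval Minimum separation between retained peaks, seconds.
#' @param min_prominence Minimum prominence in signal units, or `NULL` for
#'   the MAD-based default.
#' @return An object of class `peak_series`: `times` (strictly increasing)
#'   and `values` at the peaks.
#' @export
detect_peaks <- function(signal, min_interval = 0.25, min_prominence = NULL) {
  if (!inherits(signal, "channel_signal")) stop_respiradar("not a channel_signal")
  assert_scalar_num(min_interval, "min_interval", positive = TRUE)
  v <- signal$values
  if (is.null(min_prominence)) min_prominence <- 0.3 * stats::mad(v)
  assert_scalar_num(min_prominence, "min_prominence", nonneg = TRUE)

  n <- length(v)
  cand <- which(v[-c(1L, 2L)] < v[-c(1L, n)] & v[-c(n - 1L, n)] < v[-c(1L, n)]) + 1L
  if (length(cand) == 0L)
    return(structure(list(times = numeric(0), values = numeric(0)),
                     class = "peak_series"))

  prom <- peak_prominence(v, cand)
  keep <- prom >= min_prominence
  cand <- cand[keep]

  if (length(cand) > 1L) {
    # enforce min distance, largest peaks take priority
    ord <- order(v[cand], decreasing = TRUE)
    t_cand <- signal$times[cand]
    kept <- logical(length(cand))
    for (k in ord) {
      if (!any(kept & abs(t_cand - t_cand[k]) < min_interval)) kept[k] <- TRUE
    }
    cand <- sort(cand[kept])
  }
  structure(list(times = signal$times[cand], values = v[cand]),
            class = "peak_series")
}

# Topographic prominence of candidate local maxima `idx` (sorted) in `v`:
# height above the higher of the two key saddles, each found by descending
# from the peak until a strictly higher sample bounds the search.
peak_prominence <- function(v, idx) {
  np <- length(idx)
  # minima between consecutive candidates, plus edge minima
  seg_min <- numeric(np + 1L)
  bounds <- c(1L, idx, length(v))
  for (s in seq_len(np + 1L))
    seg_min[s] <- min(v[bounds[s]:bounds[s + 1L]])
  pv <- v[idx]
  prom <- numeric(np)
  for (k in seq_len(np)) {
    left <- seg_min[k]
    j <- k - 1L
    while (j >= 1L && pv[j] <= pv[k]) {
      left <- min(left, seg_min[j])
      j <- j - 1L
    }
    right <- seg_min[k + 1L]
    j <- k + 1L
    while (j <= np && pv[j] <= pv[k]) {
      right <- min(right, seg_min[j + 1L])
      j <- j + 1L
    }
    prom[k] <- pv[k] - max(left, right)
  }
  prom
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("Peak series: %d peaks", length(x$times)))
  if (length(x$times) > 1L)
    cat(sprintf(", median interval %.3f s", stats::median(diff(x$times))))
  cat("\n")
  invisible(x)
}
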