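#' Ground-truth respiration scenario
#'
#' Describes the breathing pattern the simulator turns into chest-wall
#' displacement: a piecewise-constant rate schedule (breaths per minute),
#' the displacement amplitude, optional cycle-to-cycle rate jitter, and
#' additive measurement noise on the displacement itself. Variability is
#' opt-in: the constructor defaults describe a perfectly regular breather.
#'
#' @param segments Rate schedule: a two-column matrix or data.frame with
#'   columns `duration` (seconds) and `rate` (bpm), one row per protocol
#'   segment; or a numeric vector `c(duration, rate)` for a single segment.
#' @param displacement_amplitude Peak chest-wall excursion in metres.
#'   Respiration moves the body surface on the order of millimetres; the
#'   default is 1 mm.
#' @param waveform Shape of one respiratory cycle: `"raised_cosine"`
#'   (default; smooth inhale/exhale bump from 0 to the amplitude and back) or
#'   `"sine"` (zero-mean sinusoid).
#' @param rate_jitter_sd Cycle-to-cycle standard deviation of the breathing
#'   rate in bpm, drawn i.i.d. Gaussian per cycle and truncated so cycle
#'   periods stay positive. 0 disables jitter.
#' @param displacement_noise_sd Additive Gaussian noise on the displacement
#'   trace, in metres. 0 disables it.
#' @param seed Integer seed making the scenario's random draws reproducible.
#'
#' @return An object of class `resp_scenario`.
#' @examples
#' sc <- resp_scenario(c(60, 60))                 # 60 s at 60 bpm
#' sc2 <- resp_scenario(rbind(c(10, 90), c(10, 54)))
#' @export
resp_scenario <- function(segments,
                          displacement_amplitude = 1e-3,
                          waveform = c("raised_cosine", "sine"),
                          rate_jitter_sd = 0,
                          displacement_noise_sd = 0,
                          seed = 1L) {
  if (is.null(dim(segments))) {
    if (length(segments) != 2L)
      stop_respiradar("a single segment must be c(duration, rate)")
    segments <- matrix(segments, nrow = 1L)
  }
  segments <- as.matrix(segments)
  if (nrow(segments) == 0L) stop_respiradar("empty scenario")
  if (ncol(segments) != 2L)
    stop_respiradar("'segments' needs columns (duration_s, rate_bpm)")
  colnames(segments) <- c("duration", "rate")
  if (any(!is.finite(segments))) stop_respiradar("non-finite segment entries")
  if (any(segments[, "duration"] <= 0)) stop_respiradar("all durations must be > 0")
  if (any(segments[, "rate"] <= 0)) stop_respiradar("all rates must be > 0")
  waveform <- match.arg(waveform)
  assert_scalar_num(displacement_amplitude, "displacement_amplitude", nonneg = TRUE)
  assert_scalar_num(rate_jitter_sd, "rate_jitter_sd", nonneg = TRUE)
  assert_scalar_num(displacement_noise_sd, "displacement_noise_sd", nonneg = TRUE)

  structure(list(
    segments = segments,
    displacement_amplitude = displacement_amplitude,
    waveform = waveform,
    rate_jitter_sd = rate_jitter_sd,
    displacement_noise_sd = displacement_noise_sd,
    seed = as.integer(seed)
  ), class = "resp_scenario")
}

#' @export
print.resp_scenario <- function(x, ...) {
  cat(sprintf("Respiration scenario: %d segment(s), %.1f s total\n",
              nrow(x$segments), scenario_duration(x)))
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %6.1f s @ %5.1f bpm\n",
                x$segments[i, "duration"], x$segments[i, "rate"]))
  cat(sprintf("  amplitude %.3g mm (%s), rate jitter sd %g bpm, displacement noise sd %.3g m, seed %d\n",
              x$displacement_amplitude * 1e3, x$waveform,
              x$rate_jitter_sd, x$displacement_noise_sd, x$seed))
  invisible(x)
}

#' Total duration of a scenario in seconds
#' @param scenario A [resp_scenario()].
#' @return Numeric scalar, seconds.
#' @export
scenario_duration <- function(scenario) {
  sum(scenario$segments[, "duration"])
}

#' Bundled scenario presets
#'
#' `"steady60"` is one minute of perfectly regular breathing at 60 bpm.
#' `"isoflurane_step"` emulates a stepped-anesthesia protocol: four 8-minute
#' segments whose rates (90, 85, 55, 80 bpm) follow the respiratory
#' depression and recovery seen when isoflurane is stepped
#' 1.7% -> 1.3% -> 2.1% -> 0.9%, with 2 bpm of breath-to-breath jitter.
#' `"isoflurane_step_short"` is the same protocol scaled to four 60-second
#' segments for quick runs.
#'
#' @param name Preset id.
#' @param seed Integer seed.
#' @return A [resp_scenario()]; for the isoflurane presets the result also
#'   carries a `levels` attribute with the concentration label per segment.
#' @export
scenario_preset <- function(name, seed = 1L) {
  presets <- c("steady60", "isoflurane_step", "isoflurane_step_short")
  if (!name %in% presets)
    stop_respiradar("unknown preset '%s'; available: %s",
                    name, paste(presets, collapse = ", "))
  sc <- switch(name,
    steady60 = resp_scenario(c(60, 60), seed = seed),
    isoflurane_step = resp_scenario(
      cbind(duration = rep(480, 4), rate = c(90, 85, 55, 80)),
      rate_jitter_sd = 2, seed = seed),
    isoflurane_step_short = resp_scenario(
      cbind(duration = rep(60, 4), rate = c(90, 85, 55, 80)),
      rate_jitter_sd = 2, seed = seed)
  )
  if (grepl("^isoflurane", name))
    attr(sc, "levels") <- c("iso-1.7", "iso-1.3", "iso-2.1", "iso-0.9")
  attr(sc, "preset") <- name
  sc
}

#' List of available scenario preset ids
#' @return Character vector.
#' @export
scenario_presets <- function() c("steady60", "isoflurane_step", "isoflurane_step_short")
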