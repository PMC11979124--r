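#' Generate a chest-wall displacement trace from a scenario
#'
#' Turns a rate schedule into a sampled displacement signal d(t): respiration
#' moves the body surface back and forth quasi-periodically about a fixed
#' standoff distance. Breath cycles are generated one at a time; each cycle's
#' rate is the scheduled rate at the cycle onset plus optional Gaussian
#' jitter, and the within-cycle phase advances linearly, so within a constant
#' segment the dominant oscillation frequency is rate/60 Hz.
#'
#' @param scenario A [resp_scenario()].
#' @param sampling_rate Sampling rate of the output grid in Hz.
#' @return An object of class `ref_trace`: list with `times` (s, uniform) and
#'   `displacement` (m), the laser-style reference signal.
#' @examples
#' ref <- generate_displacement(resp_scenario(c(10, 60)), sampling_rate = 200)
#' range(ref$displacement)  # 0 .. 1 mm for the raised-cosine waveform
#' @export
generate_displacement <- function(scenario, sampling_rate = 1092) {
  if (!inherits(scenario, "resp_scenario")) stop_respiradar("not a resp_scenario")
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  total <- scenario_duration(scenario)
  seg_end <- cumsum(scenario$segments[, "duration"])
  seg_start <- c(0, seg_end[-length(seg_end)])
  n <- floor(total * sampling_rate) + 1L
  times <- (seq_len(n) - 1L) / sampling_rate

  with_seed(scenario$seed, {
    # breath onsets: schedule rate at onset + truncated per-cycle jitter
    onsets <- 0
    repeat {
      t0 <- onsets[length(onsets)]
      if (t0 > total) break
      seg <- findInterval(t0, seg_start, rightmost.closed = FALSE)
      seg <- min(max(seg, 1L), nrow(scenario$segments))
      rate <- scenario$segments[seg, "rate"]
      if (scenario$rate_jitter_sd > 0)
        rate <- max(rate + stats::rnorm(1, 0, scenario$rate_jitter_sd), 0.1 * rate)
      onsets <- c(onsets, t0 + 60 / rate)
    }
    # cumulative cycle count, linear within each cycle
    phase <- stats::approx(onsets, seq_along(onsets) - 1, xout = times,
                           rule = 2)$y
    amp <- scenario$displacement_amplitude
    d <- switch(scenario$waveform,
      raised_cosine = amp * (1 - cos(2 * pi * phase)) / 2,
      sine = amp * sin(2 * pi * phase))
    if (scenario$displacement_noise_sd > 0)
      d <- d + stats::rnorm(n, 0, scenario$displacement_noise_sd)
    structure(list(times = times, displacement = d),
              sampling_rate = sampling_rate,
              scenario = scenario,
              class = "ref_trace")
  })
}

#' @export
print.ref_trace <- function(x, ...) {
  cat(sprintf("Displacement reference: %d samples @ %g Hz (%.1f s), range [%.3g, %.3g] mm\n",
              length(x$times), attr(x, "sampling_rate"),
              x$times[length(x$times)],
              min(x$displacement) * 1e3, max(x$displacement) * 1e3))
  invisible(x)
}

#' Simulate quadrature radar baseband channels from a displacement trace
#'
#' Applies the CW Doppler measurement model: the target at distance
#' d0 + d(t) phase-modulates the reflected carrier, and quadrature
#' demodulation yields
#' \deqn{I(t) = A \sin\theta(t), \quad Q(t) = A \cos\theta(t), \quad
#'       \theta(t) = \frac{4\pi}{\lambda_c}\,(d(t) + d_0) + \phi,}
#' where \eqn{\lambda_c} is the carrier wavelength and \eqn{\phi} the
#' residual phase of the front end. Independent Gaussian noise is then added
#' to each channel, followed by optional mid-rise ADC quantization over the
#' full-scale range \eqn{\pm(A + 4\,\mathrm{noise\_sd})}.
#'
#' @param reference A `ref_trace` on a uniform time grid.
#' @param config A [radar_config()].
#' @param seed Integer seed for the channel noise and (if unset in `config`)
#'   the residual-phase draw.
#' @return An object of class `iq_trace`: `times` (s), `i`, `q` (a.u.); the
#'   realized residual phase is stored in the `residual_phase` attribute.
#' @export
simulate_iq <- function(reference, config = radar_config(), seed = 1L) {
  if (!inherits(reference, "ref_trace")) stop_respiradar("not a ref_trace")
  if (length(reference$times) == 0L) stop_respiradar("empty reference")
  if (!is_uniform_grid(reference$times, tol = 1e-6))
    stop_respiradar("non-uniform sampling")
  with_seed(seed, {
    phi <- config$residual_phase %||% stats::runif(1, 0, 2 * pi)
    theta <- (4 * pi / config$wavelength) *
      (reference$displacement + config$nominal_distance) + phi
    i <- config$amplitude * sin(theta)
    q <- config$amplitude * cos(theta)
    if (config$noise_sd > 0) {
      i <- i + stats::rnorm(length(i), 0, config$noise_sd)
      q <- q + stats::rnorm(length(q), 0, config$noise_sd)
    }
    if (config$adc_bits > 0L) {
      fullscale <- config$amplitude + 4 * config$noise_sd
      i <- quantize_adc(i, config$adc_bits, fullscale)
      q <- quantize_adc(q, config$adc_bits, fullscale)
    }
    structure(list(times = reference$times, i = i, q = q),
              sampling_rate = attr(reference, "sampling_rate"),
              residual_phase = phi,
              config = config,
              class = "iq_trace")
  })
}

#' @export
print.iq_trace <- function(x, ...) {
  cat(sprintf("I/Q radar trace: %d samples @ %g Hz, residual phase %.4f rad\n",
              length(x$times), attr(x, "sampling_rate"),
              attr(x, "residual_phase")))
  invisible(x)
}

#' Mid-rise ADC quantization
#'
#' Maps a continuous signal to one of `2^bits` reconstruction levels evenly
#' spaced over \eqn{[-\mathrm{full\_scale}, +\mathrm{full\_scale}]}
#' (mid-rise grid), clipping out-of-range samples to the extreme levels.
#' For in-range samples the error is at most `full_scale / 2^bits`, and the
#' operation is idempotent.
#'
#' @param x Numeric signal.
#' @param bits Resolution, integer >= 1. Disabling quantization is the
#'   caller's decision (`adc_bits = 0` in [radar_config()]); `bits <= 0` here
#'   is an error rather than a silent pass-through.
#' @param full_scale Half-range of the converter, same units as `x`.
#' @return Quantized signal, same length as `x`.
#' @examples
#' quantize_adc(c(-1, 1), bits = 1, full_scale = 2)  # grid points unchanged
#' @export
quantize_adc <- function(x, bits, full_scale) {
  assert_scalar_num(bits, "bits")
  if (bits < 1 || bits != round(bits))
    stop_respiradar("'bits' must be an integer >= 1 (use adc_bits = 0 in the config to disable quantization)")
  assert_scalar_num(full_scale, "full_scale", positive = TRUE)
  nlev <- 2^bits
  step <- 2 * full_scale / nlev
  idx <- floor((x + full_scale) / step)
  idx <- pmin(pmax(idx, 0), nlev - 1)
  -full_scale + (idx + 0.5) * step
}

#' Simulate a complete recording (radar + co-registered reference)
#'
#' Convenience wrapper: generates the displacement ground truth and the I/Q
#' channels observing it, so the radar and the laser-style reference measure
#' the same motion, as in a bench validation experiment.
#'
#' @param scenario A [resp_scenario()].
#' @param config A [radar_config()].
#' @return List with elements `reference` (`ref_trace`) and `iq` (`iq_trace`).
#' @export
simulate_recording <- function(scenario, config = radar_config()) {
  ref <- generate_displacement(scenario, config$sampling_rate)
  iq <- simulate_iq(ref, config, seed = scenario$seed + 1000L)
  list(reference = ref, iq = iq)
}
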