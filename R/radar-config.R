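#' Radar sensor configuration
#'
#' Physical and acquisition constants of the simulated CW Doppler sensor.
#' The K-band module transmits a single carrier; chest-wall motion modulates
#' the phase of the reflection, which quadrature demodulation turns into two
#' baseband channels (I and Q). The wavelength is derived from the carrier as
#' \eqn{\lambda_c = c / f_c} with \eqn{c = 3 \times 10^8} m/s.
#'
#' @param carrier_frequency Carrier frequency in Hz. Default 24.15 GHz, the
#'   midpoint of the licence-free 24.05--24.25 GHz band used by compact
#'   vital-sign radar modules.
#' @param nominal_distance Standoff distance \eqn{d_0} in metres between the
#'   antenna and the resting chest wall.
#' @param residual_phase Residual phase \eqn{\phi} in radians accumulated in
#'   antennas, wiring and circuits; it sets the operating point of the I and Q
#'   channels. `NULL` (default) means "draw uniformly on \eqn{[0, 2\pi)} from
#'   the simulation seed", which reproducibly breaks the I/Q symmetry the way
#'   an uncalibrated front end does.
#' @param amplitude Received-signal amplitude \eqn{A} in arbitrary units
#'   (constant in this model).
#' @param sampling_rate Acquisition sampling rate in Hz (default 1092, the
#'   rate of the reference acquisition board).
#' @param adc_bits ADC resolution in bits (default 10). `0` disables
#'   quantization; otherwise 1--16.
#' @param noise_sd Standard deviation of additive Gaussian noise applied to
#'   each baseband channel, in the same arbitrary units as `amplitude`.
#'
#' @return An object of class `radar_config`.
#' @examples
#' cfg <- radar_config()
#' cfg$wavelength  # about 12.4 mm at 24.15 GHz
#' @export
radar_config <- function(carrier_frequency = 24.15e9,
                         nominal_distance = 0.3,
                         residual_phase = NULL,
                         amplitude = 1,
                         sampling_rate = 1092,
                         adc_bits = 10L,
                         noise_sd = 0) {
  assert_scalar_num(carrier_frequency, "carrier_frequency", positive = TRUE)
  assert_scalar_num(nominal_distance, "nominal_distance", nonneg = TRUE)
  if (!is.null(residual_phase))
    assert_scalar_num(residual_phase, "residual_phase")
  assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  assert_scalar_num(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_num(adc_bits, "adc_bits", nonneg = TRUE)
  if (adc_bits != round(adc_bits) || adc_bits > 16)
    stop_respiradar("'adc_bits' must be an integer in {0, 1..16}")
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)

  structure(list(
    carrier_frequency = carrier_frequency,
    wavelength = 3e8 / carrier_frequency,
    nominal_distance = nominal_distance,
    residual_phase = residual_phase,
    amplitude = amplitude,
    sampling_rate = sampling_rate,
    adc_bits = as.integer(adc_bits),
    noise_sd = noise_sd
  ), class = "radar_config")
}

#' @export
print.radar_config <- function(x, ...) {
  cat("CW radar configuration\n")
  cat(sprintf("  carrier: %.2f GHz (wavelength %.2f mm)\n",
              x$carrier_frequency / 1e9, x$wavelength * 1e3))
  cat(sprintf("  standoff d0: %.3f m, amplitude A: %g a.u.\n",
              x$nominal_distance, x$amplitude))
  cat(sprintf("  residual phase: %s\n",
              if (is.null(x$residual_phase)) "drawn from seed"
              else sprintf("%.4f rad", x$residual_phase)))
  cat(sprintf("  sampling: %g Hz, ADC: %s, noise sd: %g a.u.\n",
              x$sampling_rate,
              if (x$adc_bits == 0L) "off" else sprintf("%d bit", x$adc_bits),
              x$noise_sd))
  invisible(x)
}
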