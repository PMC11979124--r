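# Independent oracles used against the pipeline. These deliberately share no
# code with the package internals.

# Count breathing cycles as upward crossings of the mid-level.
count_cycles_zero_crossing <- function(values) {
  mid <- (max(values) + min(values)) / 2
  above <- values > mid
  sum(diff(above) == 1)
}

# Spectral-peak rate estimate (bpm) by direct FFT, searching the
# respiration band. Returns the estimate and the FFT bin width in bpm.
fft_rate_oracle <- function(values, fs, band = c(0.2, 3.5)) {
  x <- values - mean(values)
  n <- length(x)
  sp <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * fs / n
  in_band <- freqs >= band[1] & freqs <= band[2]
  f_peak <- freqs[in_band][which.max(sp[in_band])]
  list(bpm = 60 * f_peak, bin_bpm = 60 * fs / n)
}

# Phase unwrap (cumulative wrapped differences); used only to check the
# simulator's phase linearity.
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}

# Quick simulated recording at a constant rate.
steady_recording <- function(rate_bpm, duration = 60, noise_sd = 0.05,
                             seed = 1, fs = 1092, ...) {
  sc <- resp_scenario(c(duration, rate_bpm), seed = seed, ...)
  simulate_recording(sc, radar_config(noise_sd = noise_sd, sampling_rate = fs))
}

# Minimal stand-in inst_rate carrying only what pairing needs.
fake_rate_series <- function(times, bpm) {
  structure(list(grid_times = times, bpm = bpm,
                 quality_interp = rep(1, length(times)),
                 params = pipeline_params()),
            class = "inst_rate")
}
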