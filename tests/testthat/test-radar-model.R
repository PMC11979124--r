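# Simulator: displacement generation, I/Q measurement model, quantization.

test_that("displacement oscillates at the scheduled rate with the scheduled amplitude", {
  fs <- 200
  sc <- resp_scenario(c(60, 60), waveform = "sine", seed = 3)
  ref <- generate_displacement(sc, fs)
  expect_true(all(abs(diff(ref$times) - 1 / fs) < 1e-9))
  orc <- fft_rate_oracle(ref$displacement, fs)
  expect_lt(abs(orc$bpm - 60), orc$bin_bpm)     # fundamental at 1.000 Hz
  expect_equal(max(abs(ref$displacement)), 1e-3, tolerance = 1e-6)

  # degenerate amplitude
  flat <- generate_displacement(
    resp_scenario(c(10, 60), displacement_amplitude = 0), fs)
  expect_true(all(flat$displacement == 0))
})

test_that("cycle counts across a two-segment schedule match a zero-crossing oracle", {
  sc <- resp_scenario(rbind(c(10, 90), c(10, 54)), seed = 5)
  ref <- generate_displacement(sc, 500)
  # 15 cycles at 90 bpm + 9 at 54 bpm
  expect_lte(abs(count_cycles_zero_crossing(ref$displacement) - 24), 1)
})

test_that("per-segment spectral peak equals the segment rate within one FFT bin", {
  fs <- 300
  sc <- resp_scenario(rbind(c(40, 72), c(40, 108)), seed = 11)
  ref <- generate_displacement(sc, fs)
  for (seg in 1:2) {
    idx <- which(ref$times >= (seg - 1) * 40 & ref$times < seg * 40)
    orc <- fft_rate_oracle(ref$displacement[idx], fs)
    expect_lt(abs(orc$bpm - c(72, 108)[seg]), orc$bin_bpm)
  }
})

test_that("scenario validation rejects degenerate inputs", {
  expect_error(resp_scenario(matrix(numeric(0), ncol = 2)), "empty scenario")
  expect_error(resp_scenario(c(0, 60)), "durations")
  expect_error(resp_scenario(c(10, -5)), "rates")
  expect_error(scenario_preset("nope"), "steady60")
})

test_that("I/Q model follows theta = (4 pi / lambda)(d + d0) + phi", {
  fs <- 100
  flat <- generate_displacement(
    resp_scenario(c(2, 60), displacement_amplitude = 0), fs)

  # operating point theta = 0: I = sin(0) = 0, Q = cos(0) = 1
  cfg0 <- radar_config(nominal_distance = 0, residual_phase = 0,
                       adc_bits = 0L, sampling_rate = fs)
  iq0 <- simulate_iq(flat, cfg0)
  expect_equal(iq0$i, rep(0, length(flat$times)))
  expect_equal(iq0$q, rep(1, length(flat$times)))

  # a step of lambda/4 advances the phase by exactly pi: both channels flip sign
  cfg <- radar_config(nominal_distance = 0.3, residual_phase = 0.7,
                      adc_bits = 0L, sampling_rate = fs)
  step <- flat
  step$displacement <- step$displacement + cfg$wavelength / 4
  a <- simulate_iq(flat, cfg)
  b <- simulate_iq(step, cfg)
  expect_equal(b$i, -a$i, tolerance = 1e-12)
  expect_equal(b$q, -a$q, tolerance = 1e-12)
})

test_that("noise-free envelope satisfies I^2 + Q^2 = A^2 within quantization error", {
  ref <- generate_displacement(resp_scenario(c(10, 80), seed = 2), 1092)
  iq <- simulate_iq(ref, radar_config(adc_bits = 10L, residual_phase = 1.1))
  expect_lt(max(abs(iq$i^2 + iq$q^2 - 1)), 2^-8)
  # without quantization the identity is exact
  iq2 <- simulate_iq(ref, radar_config(adc_bits = 0L, residual_phase = 1.1))
  expect_equal(iq2$i^2 + iq2$q^2, rep(1, length(ref$times)), tolerance = 1e-12)
})

test_that("demodulated phase is affine in displacement for mm-scale motion", {
  ref <- generate_displacement(
    resp_scenario(c(30, 60), waveform = "sine", seed = 4), 400)
  iq <- simulate_iq(ref, radar_config(adc_bits = 0L, residual_phase = 0.3,
                                      sampling_rate = 400))
  theta <- unwrap_phase(atan2(iq$i, iq$q))
  expect_gt(stats::cor(theta, ref$displacement), 0.9999)
})

test_that("simulation is deterministic given scenario, config, seed", {
  sc <- resp_scenario(c(20, 75), rate_jitter_sd = 2,
                      displacement_noise_sd = 1e-5, seed = 42)
  cfg <- radar_config(noise_sd = 0.05)
  r1 <- simulate_recording(sc, cfg)
  r2 <- simulate_recording(sc, cfg)
  expect_identical(r1$reference$displacement, r2$reference$displacement)
  expect_identical(r1$iq$i, r2$iq$i)
  expect_identical(r1$iq$q, r2$iq$q)
})

test_that("simulate_iq rejects a non-uniform reference grid", {
  ref <- generate_displacement(resp_scenario(c(5, 60)), 100)
  ref$times[10] <- ref$times[10] + 0.003
  expect_error(simulate_iq(ref, radar_config()), "non-uniform sampling")
})

test_that("mid-rise ADC quantization honours its contract", {
  # grid points map to themselves
  expect_equal(quantize_adc(c(-1, 1), bits = 1, full_scale = 2), c(-1, 1))
  # resolution: at most 2^10 distinct outputs, error bounded by fs/2^bits
  x <- seq(-1, 1, length.out = 5000)
  qx <- quantize_adc(x, 10, 1)
  expect_lte(length(unique(qx)), 1024)
  expect_lte(max(abs(qx - x)), 1 / 1024)
  # idempotence on random vectors, including out-of-range samples
  set.seed(9)
  for (bits in c(3, 10)) {
    z <- stats::rnorm(300, sd = 2)
    q1 <- quantize_adc(z, bits, 1.5)
    expect_identical(quantize_adc(q1, bits, 1.5), q1)
  }
  # disabling quantization is explicit, not a silent pass-through
  expect_error(quantize_adc(1:3, 0, 1), "adc_bits = 0")
})

test_that("radar_config derives the wavelength and validates its fields", {
  cfg <- radar_config()
  expect_equal(cfg$wavelength, 3e8 / 24.15e9)
  expect_error(radar_config(adc_bits = 20), "adc_bits")
  expect_error(radar_config(sampling_rate = -1), "sampling_rate")
})
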