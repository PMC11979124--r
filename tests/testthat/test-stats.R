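# Agreement statistics and group comparisons.

test_that("pairing restricts both series to their common overlap", {
  a <- fake_rate_series(0:100, rep(60, 101))
  b <- fake_rate_series(50:150, rep(60, 101))
  p <- pair_series(a, b, grid_rate = 1)
  expect_length(p$grid_times, 51)
  expect_equal(range(p$grid_times), c(50, 100))
  expect_true(all(p$radar_bpm - p$reference_bpm == 0))

  c <- fake_rate_series(200:210, rep(60, 11))
  expect_error(pair_series(a, c), "overlap")
})

test_that("radar-path and reference-path rates agree on a shared simulation", {
  sc <- resp_scenario(rbind(c(45, 88), c(45, 62)), rate_jitter_sd = 2, seed = 23)
  rec <- simulate_recording(sc, radar_config(noise_sd = 0.05))
  radar <- analyze_recording(rec, channel = "auto")
  refr <- analyze_recording(rec, channel = "R")
  p <- pair_series(radar, refr, grid_rate = 1)
  expect_lt(mean(abs(p$radar_bpm - p$reference_bpm)), 1)
})

test_that("Bland-Altman limits use the sample sd and the stated sign convention", {
  ident <- fake_rate_series(0:60, rep(70, 61))
  ba <- bland_altman(pair_series(ident, ident))
  expect_equal(c(ba$mean_difference, ba$loa_low, ba$loa_high), c(0, 0, 0))

  radar <- fake_rate_series(0:1, c(61, 59))
  refr <- fake_rate_series(0:1, c(60, 60))
  ba <- bland_altman(pair_series(radar, refr))       # differences -1, +1
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)

  # antisymmetry under swapping the two methods
  ba2 <- bland_altman(pair_series(radar, refr), sign = "radar - reference")
  expect_equal(ba2$mean_difference, -ba$mean_difference)
  expect_equal(ba2$loa_low, -ba$loa_high)
  expect_equal(ba2$loa_high, -ba$loa_low)
})

test_that("error metrics match hand computation and their invariants", {
  ident <- fake_rate_series(0:10, rep(70, 11))
  em <- error_metrics(pair_series(ident, ident))
  expect_equal(em$rmse, 0)
  expect_equal(em$mape, 0)
  expect_equal(em$pearson_r, 1)

  radar <- fake_rate_series(0:1, c(50, 60))
  refr <- fake_rate_series(0:1, c(55, 66))
  em <- error_metrics(pair_series(radar, refr), mape_denominator = "radar")
  expect_equal(em$rmse, sqrt((25 + 36) / 2), tolerance = 1e-12)
  expect_equal(em$mape, 10, tolerance = 1e-12)

  # rmse >= |mean difference|, equality iff constant differences
  set.seed(2)
  for (k in 1:10) {
    r <- fake_rate_series(0:20, stats::runif(21, 50, 90))
    f <- fake_rate_series(0:20, r$bpm + stats::rnorm(21))
    p <- pair_series(r, f)
    expect_gte(error_metrics(p)$rmse,
               abs(bland_altman(p)$mean_difference) - 1e-12)
  }

  # Pearson r invariant to positive affine rescaling
  r <- fake_rate_series(0:20, stats::runif(21, 50, 90))
  f <- fake_rate_series(0:20, r$bpm + stats::rnorm(21))
  r2 <- fake_rate_series(0:20, 3 * r$bpm + 7)
  expect_equal(error_metrics(pair_series(r, f))$pearson_r,
               error_metrics(pair_series(r2, f))$pearson_r, tolerance = 1e-12)

  zr <- fake_rate_series(0:2, c(60, 0, 60))
  zf <- fake_rate_series(0:2, c(60, 60, 60))
  expect_error(error_metrics(pair_series(zr, zf)), "zero radar value at t = 1")
})

test_that("Kruskal-Wallis + Dunn behaves on degenerate and separated groups", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  gc <- kruskal_posthoc(same)
  expect_gt(gc$kw_p, 0.9)
  expect_equal(gc$stars["a", "b"], "ns")
  expect_true(all(diag(gc$posthoc) == 1))
  expect_equal(gc$posthoc, t(gc$posthoc))

  set.seed(5)
  far <- list(hi = stats::rnorm(100, 90, 2), lo = stats::rnorm(100, 55, 2))
  gc <- kruskal_posthoc(far)
  expect_lt(gc$kw_p, 0.001)
  expect_equal(gc$stars["hi", "lo"], "***")

  expect_error(kruskal_posthoc(list(a = 1:5)), "at least 2 levels")
  expect_error(kruskal_posthoc(list(a = 1:5, b = 2)), ">= 2 samples")
})

test_that("Dunn z agrees with a frozen hand computation and with KW for k = 2", {
  # {1,2,3} vs {4,5,6}: pooled ranks 1..6, mean ranks 2 and 5, no ties;
  # z = (5 - 2) / sqrt(6*7/12 * (1/3 + 1/3)) = 1.96396
  gc <- kruskal_posthoc(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(abs(gc$posthoc_z["a", "b"]), 3 / sqrt(3.5 * 2 / 3),
               tolerance = 1e-12)
  # for two tie-free groups, Dunn z^2 equals the KW statistic
  set.seed(7)
  g <- list(x = stats::rnorm(12), y = stats::rnorm(15, 0.8))
  gc <- kruskal_posthoc(g)
  expect_equal(gc$posthoc_z["x", "y"]^2, gc$kw_statistic, tolerance = 1e-9)
})

test_that("a four-level stepped protocol separates the depressed level", {
  set.seed(11)
  g <- list(`iso-1.7` = stats::rnorm(100, 90, 3),
            `iso-1.3` = stats::rnorm(100, 85, 3),
            `iso-2.1` = stats::rnorm(100, 55, 3),
            `iso-0.9` = stats::rnorm(100, 80, 3))
  gc <- kruskal_posthoc(g)
  expect_lt(gc$kw_p, 0.001)
  expect_lt(gc$posthoc["iso-1.7", "iso-2.1"], 0.05)
  expect_lt(gc$posthoc["iso-1.7", "iso-0.9"], 0.05)
})

test_that("schedule splitting assigns samples to the active level", {
  fit <- fake_rate_series(seq(0, 39.9, by = 0.1), rep(c(90, 60), each = 200))
  sched <- level_schedule(c(20, 20), c("a", "b"))
  g <- split_by_level(fit, sched)
  expect_equal(names(g), c("a", "b"))
  expect_true(all(g$a == 90))
  expect_true(all(g$b == 60))
  g2 <- split_by_level(fit, sched, sample_every = 1)
  expect_length(g2$a, 20)
})
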