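#' Pair radar and reference rate series on a common grid
#'
#' Resamples two instantaneous-rate series onto the common overlap of their
#' time spans at `grid_rate` (linear interpolation), discarding everything
#' outside the overlap. The default 1 Hz pairing grid yields roughly one
#' pair per breath at anesthetized-rodent rates.
#'
#' @param radar,reference `inst_rate` objects covering overlapping spans.
#' @param grid_rate Pairing grid rate in Hz.
#' @return Object of class `paired_rates`: `grid_times`, `radar_bpm`,
#'   `reference_bpm`.
#' @export
pair_series <- function(radar, reference, grid_rate = 1) {
  stopifnot(inherits(radar, "inst_rate"), inherits(reference, "inst_rate"))
  assert_scalar_num(grid_rate, "grid_rate", positive = TRUE)
  lo <- max(radar$grid_times[1], reference$grid_times[1])
  hi <- min(radar$grid_times[length(radar$grid_times)],
            reference$grid_times[length(reference$grid_times)])
  if (hi <= lo) stop_respiradar("no temporal overlap between series")
  grid <- seq(lo, hi, by = 1 / grid_rate)
  rb <- stats::approx(radar$grid_times, radar$bpm, xout = grid)$y
  fb <- stats::approx(reference$grid_times, reference$bpm, xout = grid)$y
  structure(list(grid_times = grid, radar_bpm = rb, reference_bpm = fb),
            class = "paired_rates")
}

#' @export
print.paired_rates <- function(x, ...) {
  cat(sprintf("Paired rates: %d pairs over [%.1f, %.1f] s\n",
              length(x$grid_times), x$grid_times[1],
              x$grid_times[length(x$grid_times)]))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Computes the mean method difference and the conventional 95% limits of
#' agreement, mean(d) +/- 1.96 sd(d) with the sample (n-1) standard
#' deviation. The sign convention is recorded in the result; the default
#' `"reference - radar"` means positive differences indicate the reference
#' reading above the radar.
#'
#' @param pairs A [pair_series()] result (n >= 2).
#' @param sign `"reference - radar"` (default) or `"radar - reference"`.
#' @return List: `n_pairs`, `mean_difference`, `sd_difference`, `loa_low`,
#'   `loa_high`, `sign`.
#' @export
bland_altman <- function(pairs, sign = c("reference - radar", "radar - reference")) {
  sign <- match.arg(sign)
  stopifnot(inherits(pairs, "paired_rates"))
  n <- length(pairs$grid_times)
  if (n < 2L) stop_respiradar("need at least 2 pairs")
  d <- pairs$reference_bpm - pairs$radar_bpm
  if (sign == "radar - reference") d <- -d
  md <- mean(d)
  s <- stats::sd(d)
  list(n_pairs = n, mean_difference = md, sd_difference = s,
       loa_low = md - 1.96 * s, loa_high = md + 1.96 * s, sign = sign)
}

#' Radar-vs-reference error metrics
#'
#' RMSE of the paired differences, mean absolute percentage error, and the
#' Pearson correlation between the two series. The MAPE denominator follows
#' the convention of expressing the error as a percentage of the radar
#' value; a reference-denominator option is provided.
#'
#' @param pairs A [pair_series()] result.
#' @param mape_denominator `"radar"` (default) or `"reference"`.
#' @return List: `rmse` (bpm), `mape` (percent), `pearson_r`.
#' @export
error_metrics <- function(pairs, mape_denominator = c("radar", "reference")) {
  mape_denominator <- match.arg(mape_denominator)
  stopifnot(inherits(pairs, "paired_rates"))
  if (length(pairs$grid_times) < 2L) stop_respiradar("need at least 2 pairs")
  d <- pairs$reference_bpm - pairs$radar_bpm
  den <- if (mape_denominator == "radar") pairs$radar_bpm else pairs$reference_bpm
  if (any(den == 0)) {
    bad <- pairs$grid_times[den == 0]
    stop_respiradar("zero %s value at t = %s s; MAPE undefined",
                    mape_denominator,
                    paste(utils::head(signif(bad, 6), 5), collapse = ", "))
  }
  rmse <- sqrt(mean(d^2))
  mape <- 100 * mean(abs(d) / abs(den))
  r <- if (all(d == 0)) 1 else
    suppressWarnings(stats::cor(pairs$radar_bpm, pairs$reference_bpm))
  list(rmse = rmse, mape = mape, pearson_r = r)
}

#' Full agreement report between a radar and a reference rate series
#'
#' Bundles [bland_altman()] and [error_metrics()] into one report mirroring
#' the usual validation-table layout (RMSE, MAPE, correlation coefficient,
#' 95% limits of agreement, mean difference).
#'
#' @param pairs A [pair_series()] result.
#' @inheritParams bland_altman
#' @inheritParams error_metrics
#' @return Object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, sign = "reference - radar",
                             mape_denominator = "radar") {
  ba <- bland_altman(pairs, sign)
  em <- error_metrics(pairs, mape_denominator)
  structure(c(ba, em, list(mape_denominator = mape_denominator)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Radar vs reference agreement\n")
  cat(sprintf("  n pairs                         %d\n", x$n_pairs))
  cat(sprintf("  Root mean square error (RMSE)   %.2f bpm\n", x$rmse))
  cat(sprintf("  Mean absolute %% error (MAPE)    %.2f%% (of %s)\n",
              x$mape, x$mape_denominator))
  cat(sprintf("  Correlation coefficient         %.3f\n", x$pearson_r))
  cat(sprintf("  95%% limits of agreement         %.2f to %.2f bpm\n",
              x$loa_low, x$loa_high))
  cat(sprintf("  Mean difference (%s) %.3f bpm\n", x$sign, x$mean_difference))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pair means, with the mean difference (solid) and the
#' 95% limits of agreement (dashed).
#'
#' @param x An `agreement_report`.
#' @param pairs The [pair_series()] result the report was computed from.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, pairs, ...) {
  d <- pairs$reference_bpm - pairs$radar_bpm
  if (x$sign == "radar - reference") d <- -d
  m <- (pairs$reference_bpm + pairs$radar_bpm) / 2
  graphics::plot(m, d, pch = 20, cex = 0.5,
                 xlab = "mean of methods [bpm]",
                 ylab = sprintf("difference (%s) [bpm]", x$sign),
                 main = "Bland-Altman", ...)
  graphics::abline(h = x$mean_difference, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}
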