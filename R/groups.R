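#' Kruskal-Wallis test with Dunn post-hoc comparisons across protocol levels
#'
#' Tests whether the respiratory-rate distribution differs across anesthesia
#' protocol levels (Kruskal-Wallis rank test) and, pairwise, which levels
#' differ (Dunn's rank-sum z test with tie correction and multiplicity
#' adjustment). Significance stars follow the usual mapping
#' (`***` p < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise).
#'
#' @param rates_by_level Named list: one numeric vector of bpm samples per
#'   protocol level (>= 2 levels, >= 2 samples each).
#' @param alpha Significance level used for the star annotation cutoff.
#' @param p_adjust Multiplicity adjustment for the post-hoc p-values:
#'   `"holm"` (default) or `"bonferroni"`.
#' @return Object of class `group_comparison`: `kw_statistic`, `kw_df`,
#'   `kw_p`, `posthoc` (symmetric matrix of adjusted p-values, unit
#'   diagonal), `posthoc_z`, `stars` (character matrix), `alpha`.
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(30, 90, 3), b = rnorm(30, 85, 3), c = rnorm(30, 55, 3))
#' kruskal_posthoc(g)
#' @export
kruskal_posthoc <- function(rates_by_level, alpha = 0.05,
                            p_adjust = c("holm", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.list(rates_by_level) || length(rates_by_level) < 2L)
    stop_respiradar("need at least 2 levels")
  if (is.null(names(rates_by_level)))
    names(rates_by_level) <- paste0("level", seq_along(rates_by_level))
  ns <- vapply(rates_by_level, length, 1L)
  if (any(ns < 2L))
    stop_respiradar("every level needs >= 2 samples (offending: %s)",
                    paste(names(rates_by_level)[ns < 2L], collapse = ", "))
  kw <- stats::kruskal.test(rates_by_level)
  dunn <- dunn_test(rates_by_level, p_adjust)
  stars <- apply(dunn$p, c(1, 2), function(p)
    if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < alpha) "*" else "ns")
  diag(stars) <- ""
  structure(list(
    levels = names(rates_by_level),
    n = ns,
    kw_statistic = unname(kw$statistic),
    kw_df = unname(kw$parameter),
    kw_p = kw$p.value,
    posthoc = dunn$p,
    posthoc_z = dunn$z,
    p_adjust = p_adjust,
    stars = stars,
    alpha = alpha
  ), class = "group_comparison")
}

# Dunn's post-hoc z statistics on pooled ranks with tie correction:
#   z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j)),
#   T = sum(t^3 - t) / (12 (N - 1)) over tie groups.
dunn_test <- function(groups, p_adjust) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)[names(groups)]
  n <- vapply(groups, length, 1L)
  k <- length(groups)
  z <- p <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  pr <- c()
  idx <- which(upper.tri(z), arr.ind = TRUE)
  for (row in seq_len(nrow(idx))) {
    i <- idx[row, 1]; j <- idx[row, 2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z[i, j] <- z[j, i] <- (rbar[i] - rbar[j]) / se
    pr <- c(pr, 2 * stats::pnorm(-abs(z[i, j])))
  }
  pr <- stats::p.adjust(pr, method = p_adjust)
  for (row in seq_len(nrow(idx)))
    p[idx[row, 1], idx[row, 2]] <- p[idx[row, 2], idx[row, 1]] <- pr[row]
  diag(p) <- 1
  diag(z) <- 0
  list(z = z, p = p)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Respiratory rate by protocol level\n")
  cat(sprintf("  levels: %s (n = %s)\n",
              paste(x$levels, collapse = ", "),
              paste(x$n, collapse = ", ")))
  cat(sprintf("  Kruskal-Wallis chi-squared = %.3f, df = %d, p = %.3g\n",
              x$kw_statistic, x$kw_df, x$kw_p))
  cat(sprintf("  Post-hoc (Dunn, %s-adjusted):\n", x$p_adjust))
  m <- matrix(sprintf("%.3g %s", x$posthoc, x$stars),
              nrow = nrow(x$posthoc), dimnames = dimnames(x$posthoc))
  diag(m) <- "-"
  print(m[-1, -ncol(m), drop = FALSE], quote = FALSE)
  invisible(x)
}

#' Split a bpm series by a protocol-level schedule
#'
#' Assigns each grid sample of an `inst_rate` to the protocol level active
#' at that time and returns the per-level bpm samples, optionally decimated.
#'
#' @param series An `inst_rate`.
#' @param schedule Data frame with columns `start` (s), `end` (s), `level`
#'   (label), as produced by [level_schedule()].
#' @param sample_every Keep one sample every this many seconds (default:
#'   every grid sample).
#' @return Named list of bpm vectors, one per level in schedule order.
#' @export
split_by_level <- function(series, schedule, sample_every = NULL) {
  stopifnot(inherits(series, "inst_rate"))
  t <- series$grid_times
  b <- series$bpm
  if (!is.null(sample_every)) {
    step <- max(1L, round(sample_every * series$params$grid_rate))
    keep <- seq(1L, length(t), by = step)
    t <- t[keep]; b <- b[keep]
  }
  out <- lapply(seq_len(nrow(schedule)), function(i)
    b[t >= schedule$start[i] & t < schedule$end[i]])
  names(out) <- as.character(schedule$level)
  out
}

#' Build a protocol-level schedule from a scenario or durations
#'
#' @param durations Segment durations in seconds.
#' @param levels Level labels, same length.
#' @return Data frame with `start`, `end`, `level`.
#' @export
level_schedule <- function(durations, levels) {
  stopifnot(length(durations) == length(levels), all(durations > 0))
  end <- cumsum(durations)
  data.frame(start = c(0, end[-length(end)]), end = end,
             level = as.character(levels), stringsAsFactors = FALSE)
}
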