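# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. All seeded functions in the package route through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Uniform-grid check used by every consumer of sampled traces.
# Tolerance is relative jitter on the sampling interval.
is_uniform_grid <- function(times, tol = 0.01) {
  if (length(times) < 2L) return(TRUE)
  dt <- diff(times)
  md <- stats::median(dt)
  md > 0 && all(abs(dt - md) <= tol * md)
}

stop_respiradar <- function(msg, ..., call. = FALSE) {
  stop(sprintf(msg, ...), call. = call.)
}

assert_scalar_num <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_respiradar("'%s' must be a single finite number", name)
  if (positive && x <= 0) stop_respiradar("'%s' must be > 0", name)
  if (nonneg && x < 0) stop_respiradar("'%s' must be >= 0", name)
  invisible(x)
}
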