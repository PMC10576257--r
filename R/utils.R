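#' @keywords internal
"_PACKAGE"

# Shared validation helpers. All user-facing errors go through stop(call. = FALSE)
# so messages read as contract violations, not tracebacks.

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name), call. = FALSE)
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Normal truncated to (lower, Inf), by inverse-CDF so draws stay reproducible
# and vectorized.
rtnorm <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

# Even-odd (ray casting) point-in-polygon; half-open convention: a point on a
# "lower" edge counts as inside, on the opposite edge as outside, so abutting
# ROIs never double-claim a punctum.
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  stopifnot(n >= 3L, length(poly_y) == n)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > py) != (poly_y[j] > py)) &
      (px < (poly_x[j] - poly_x[i]) * (py - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

se_mean <- function(x) stats::sd(x) / sqrt(length(x))
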