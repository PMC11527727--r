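# Internal helpers shared across modules.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

stopifnot_scalar <- function(x, name, finite = TRUE, nonneg = FALSE, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L)
    stop(sprintf("`%s` must be a single numeric value", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Run `expr` under a fixed RNG seed and restore the caller's RNG state after.
# All package randomness flows through this so no global state leaks.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Trapezoidal integral of y over x (uniform or not).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples to integrate", call. = FALSE)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
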