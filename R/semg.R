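#' Uniformly sampled surface-EMG record
#'
#' @param t Time stamps (s), uniform.
#' @param v Voltage (mV), same length as `t`.
#' @param fs Sampling rate (Hz); inferred from `t` when `NULL`.
#' @param muscle Muscle label, one of `"FCU"`, `"ECU"`, `"FCR"` (or any
#'   string for non-standard electrodes).
#' @param condition Resistance condition label: `"none"`, `"low"` or
#'   `"high"`.
#' @param subject Subject identifier.
#' @return An object of class `emg_record`.
#' @export
emg_record <- function(t, v, fs = NULL, muscle = "FCU", condition = "none",
                       subject = "S1") {
  if (length(t) != length(v))
    stop("`t` and `v` must have equal length", call. = FALSE)
  if (length(t) < 2L) stop("record needs at least two samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
  if (max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
    stop("non-uniform sampling", call. = FALSE)
  if (is.null(fs)) fs <- 1 / mean(dt)
  structure(list(t = as.numeric(t), v = as.numeric(v), fs = fs,
                 muscle = muscle, condition = condition, subject = subject),
            class = "emg_record")
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("sEMG record: %s/%s subject %s, %d samples @ %g Hz\n",
              x$muscle, x$condition, x$subject, length(x$v), x$fs))
  invisible(x)
}

# Daubechies-4 (8-tap) orthogonal analysis filters.
.db4_lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
             -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
             0.7148465705529157, 0.2303778133088965)
.db4_hi <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
             -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
             -0.0328830116668852, -0.010597401785069032)

# One periodized analysis step: x (even length) -> list(a, d).
dwt_step <- function(x) {
  N <- length(x)
  L <- length(.db4_lo)
  idx <- outer(2 * seq_len(N / 2) + L / 2 - 2, seq_len(L) - 1, "-") %% N + 1
  xm <- matrix(x[idx], nrow = N / 2)
  list(a = drop(xm %*% .db4_lo), d = drop(xm %*% .db4_hi))
}

# Inverse of dwt_step (transpose of the orthogonal analysis map).
idwt_step <- function(a, d) {
  N <- 2L * length(a)
  L <- length(.db4_lo)
  x <- numeric(N)
  for (k in seq_along(a)) {
    pos <- (2 * k + L / 2 - 2 - (seq_len(L) - 1)) %% N + 1
    x[pos] <- x[pos] + a[k] * .db4_lo + d[k] * .db4_hi
  }
  x
}

# Multi-level periodized db4 decomposition. Returns list(a, d = list of
# detail vectors finest-last, n = original length, pad).
db4_decompose <- function(x, level) {
  n <- length(x)
  block <- 2L^level
  pad <- (block - n %% block) %% block
  if (pad > 0) x <- c(x, rev(x)[seq_len(pad)])  # reflect-pad to a multiple
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    s <- dwt_step(a)
    a <- s$a
    details[[level - j + 1L]] <- s$d  # store coarsest first
  }
  list(a = a, d = details, n = n, pad = pad)
}

db4_reconstruct <- function(dec) {
  a <- dec$a
  for (j in seq_along(dec$d)) a <- idwt_step(a, dec$d[[j]])
  a[seq_len(dec$n)]
}

#' Wavelet denoising of an sEMG record
#'
#' Orthogonal discrete wavelet decomposition with the Daubechies db4 basis
#' (level 2 by default), soft thresholding of the detail coefficients, and
#' reconstruction. The threshold is the universal rule
#' `sigma * sqrt(2 log N)` with the noise scale `sigma` estimated from the
#' median absolute deviation of the finest-level details
#' (`MAD / 0.6745`). Because the transform is orthogonal and shrinkage only
#' contracts coefficients, the output energy never exceeds the input
#' energy.
#'
#' @param rec An [emg_record()].
#' @param basis Wavelet basis; only `"db4"` is provided.
#' @param level Decomposition depth (the record must be at least
#'   `2^level` samples long).
#' @param threshold `"universal"` (default) or a numeric threshold value.
#' @return A denoised [emg_record()] of the same length.
#' @export
wavelet_denoise <- function(rec, basis = "db4", level = 2,
                            threshold = "universal") {
  if (!inherits(rec, "emg_record"))
    stop("`rec` must be created with emg_record()", call. = FALSE)
  if (!identical(basis, "db4"))
    stop(sprintf("unknown wavelet basis '%s'", basis), call. = FALSE)
  if (length(rec$v) < 2^level)
    stop("record too short for the requested decomposition level", call. = FALSE)
  dec <- db4_decompose(rec$v, level)
  finest <- dec$d[[length(dec$d)]]
  thr <- if (identical(threshold, "universal")) {
    sigma <- stats::median(abs(finest)) / 0.6745
    sigma * sqrt(2 * log(length(rec$v)))
  } else {
    stopifnot_scalar(threshold, "threshold", nonneg = TRUE)
    threshold
  }
  dec$d <- lapply(dec$d, function(d) sign(d) * pmax(abs(d) - thr, 0))
  out <- rec
  out$v <- db4_reconstruct(dec)
  out
}

#' Integrated EMG over a time window
#'
#' The muscle-activation index `iEMG = integral of |v(t)| dt` over the
#' window, computed with the trapezoidal rule, in mV s. By default the
#' window mean is removed before rectification so a DC electrode offset
#' does not inflate the index; disable with `dc_remove = FALSE` when the
#' record is already offset-free or pre-rectified.
#'
#' @param rec An [emg_record()].
#' @param window Length-2 numeric `(t_start, t_end)` in seconds, within the
#'   record span; `NULL` integrates the full record.
#' @param dc_remove Subtract the window mean before rectification.
#' @return List with `value` (mV s) and `window` (s).
#' @export
iemg <- function(rec, window = NULL, dc_remove = TRUE) {
  if (!inherits(rec, "emg_record"))
    stop("`rec` must be created with emg_record()", call. = FALSE)
  if (is.null(window)) window <- range(rec$t)
  if (length(window) != 2 || window[2] <= window[1])
    stop("`window` must be an increasing (t_start, t_end) pair", call. = FALSE)
  sel <- rec$t >= window[1] & rec$t <= window[2]
  if (sum(sel) < 2L) stop("window contains fewer than two samples", call. = FALSE)
  v <- rec$v[sel]
  if (dc_remove) v <- v - mean(v)
  list(value = trapz(rec$t[sel], abs(v)), window = window)
}

#' Percent iEMG increase of each condition over the no-resistance baseline
#'
#' @param values Named numeric vector of iEMG values (mV s) containing a
#'   `baseline` entry.
#' @param baseline Name of the baseline condition (default `"none"`).
#' @return Named numeric vector of percent increases,
#'   `100 * (value / baseline - 1)`, excluding the baseline entry.
#' @export
condition_comparison <- function(values, baseline = "none") {
  if (is.null(names(values)) || !baseline %in% names(values))
    stop(sprintf("`values` must be named and include the baseline '%s'",
                 baseline), call. = FALSE)
  b <- values[[baseline]]
  if (!is.finite(b) || b <= 0)
    stop("baseline iEMG must be positive", call. = FALSE)
  out <- 100 * (values[setdiff(names(values), baseline)] / b - 1)
  out
}

#' Across-subject summary of iEMG values
#'
#' @param values Numeric vector, one iEMG value per subject (n >= 2 for a
#'   defined standard deviation).
#' @return Named numeric vector `c(mean, sd, n)`; `sd` is the sample
#'   standard deviation (n - 1 denominator) and is `NA` with a warning for
#'   a single subject.
#' @export
summarize_subjects <- function(values) {
  n <- length(values)
  if (n < 1L) stop("no values supplied", call. = FALSE)
  s <- if (n < 2L) {
    warning("standard deviation undefined for a single subject")
    NA_real_
  } else stats::sd(values)
  c(mean = mean(values), sd = s, n = n)
}
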