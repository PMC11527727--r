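#' Configuration for a synthetic reciprocating joint-angle trace
#'
#' Describes a training session of `n_reps` reciprocations. Each repetition
#' occupies `rep_period` seconds and consists of a raised-cosine (Hann)
#' positive lobe followed by a mirrored negative lobe, so the trace reaches
#' `+A_i` then `-A_i` and returns smoothly to zero; Gaussian sensor noise is
#' added on top.
#'
#' @param pattern Motion-pattern label.
#' @param per_rep_amplitudes Peak amplitude of each repetition (degrees);
#'   its length defines the number of repetitions.
#' @param rep_period Duration of one reciprocation (s).
#' @param fs Sampling rate (Hz).
#' @param noise_sd Additive Gaussian noise standard deviation (degrees).
#' @param joint Joint label.
#' @param seed Integer RNG seed; the trace is deterministic given the seed.
#' @return An object of class `angle_trace_config`.
#' @export
angle_trace_config <- function(pattern = "fe", per_rep_amplitudes = rep(50, 5),
                               rep_period = 4, fs = 50, noise_sd = 0.5,
                               joint = "wrist", seed = 1L) {
  stopifnot_scalar(rep_period, "rep_period", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (length(per_rep_amplitudes) < 1L)
    stop("need at least one repetition amplitude", call. = FALSE)
  structure(list(pattern = pattern, per_rep_amplitudes = per_rep_amplitudes,
                 n_reps = length(per_rep_amplitudes), rep_period = rep_period,
                 fs = fs, noise_sd = noise_sd, joint = joint,
                 seed = as.integer(seed)),
            class = "angle_trace_config")
}

#' Generate a synthetic joint-angle trace
#'
#' @param cfg An [angle_trace_config()].
#' @return A [joint_angle_series()].
#' @export
gen_angle_trace <- function(cfg) {
  if (!inherits(cfg, "angle_trace_config"))
    stop("`cfg` must be created with angle_trace_config()", call. = FALSE)
  dt <- 1 / cfg$fs
  t <- seq(0, cfg$n_reps * cfg$rep_period, by = dt)
  angle <- numeric(length(t))
  half <- cfg$rep_period / 2
  for (i in seq_len(cfg$n_reps)) {
    t0 <- (i - 1) * cfg$rep_period
    phase <- (t - t0) / half          # 0..2 within this repetition
    in_pos <- phase >= 0 & phase < 1
    in_neg <- phase >= 1 & phase < 2
    A <- cfg$per_rep_amplitudes[i]
    angle[in_pos] <- angle[in_pos] + A * (1 - cos(2 * pi * phase[in_pos])) / 2
    angle[in_neg] <- angle[in_neg] - A * (1 - cos(2 * pi * (phase[in_neg] - 1))) / 2
  }
  if (cfg$noise_sd > 0)
    angle <- angle + with_seed(cfg$seed, stats::rnorm(length(t), 0, cfg$noise_sd))
  joint_angle_series(t, angle, joint = cfg$joint, pattern = cfg$pattern,
                     fs = cfg$fs)
}

#' Replica configuration of the half-compliant counting protocol
#'
#' Ten reciprocations for an elbow/shoulder pattern of which only the first
#' five satisfy the pattern's threshold pair: compliant repetitions peak 15
#' degrees above the upper threshold (and, being bipolar, overshoot any
#' negative lower bound), non-compliant ones peak 5 degrees below the upper
#' threshold so they are never armed and must not be counted.
#'
#' @param pattern One of `"elbow_fe"`, `"elbow_abd_add"`, `"shoulder_fe"`,
#'   `"shoulder_rot"` (see [default_thresholds()]).
#' @param noise_sd Sensor noise (degrees).
#' @param seed Integer RNG seed.
#' @return An [angle_trace_config()] with 10 repetitions.
#' @export
counting_protocol_config <- function(pattern = "elbow_fe", noise_sd = 0.5,
                                     seed = 1L) {
  thr <- default_thresholds()[[match.arg(pattern, names(default_thresholds()))]]
  amps <- c(rep(thr$upper + 15, 5), rep(thr$upper - 5, 5))
  joint <- if (startsWith(pattern, "elbow")) "elbow" else "shoulder"
  angle_trace_config(pattern = pattern, per_rep_amplitudes = amps,
                     rep_period = 4, fs = 50, noise_sd = noise_sd,
                     joint = joint, seed = seed)
}

#' Configuration for surrogate burst-structured sEMG
#'
#' The surrogate signal is amplitude-modulated band-limited Gaussian noise:
#' a carrier confined to `carrier_band` is modulated by per-repetition
#' raised-cosine envelopes of height `base_envelope * condition_scale`,
#' separated by rest intervals, plus additive wideband noise. This carries
#' exactly the properties the downstream analyses consume — burst timing,
#' envelope scale, noise floor — and makes no claim to motor-unit
#' physiology.
#'
#' @param n_reps Number of contraction bursts.
#' @param burst_duration Burst length (s).
#' @param inter_burst Rest between bursts (s).
#' @param fs Sampling rate (Hz).
#' @param base_envelope Envelope peak of the no-resistance condition (mV).
#' @param condition_scales Named multiplicative envelope factors per
#'   condition; the baseline condition must have scale 1.
#' @param carrier_band Carrier frequency band (Hz), within `(0, fs/2)`.
#' @param noise_sd Additive white-noise standard deviation (mV). The
#'   default 0.005 mV (5 uV RMS) is the baseline noise of a good
#'   surface-EMG chain with proper skin preparation.
#' @param seed Integer RNG seed.
#' @return An object of class `semg_config`.
#' @export
semg_config <- function(n_reps = 5, burst_duration = 1, inter_burst = 1,
                        fs = 1000, base_envelope = 0.5,
                        condition_scales = c(none = 1, low = 1.3, high = 1.9),
                        carrier_band = c(20, 450), noise_sd = 0.005,
                        seed = 1L) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(base_envelope, "base_envelope", nonneg = TRUE)
  stopifnot_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (any(condition_scales <= 0)) stop("condition scales must be > 0", call. = FALSE)
  if (is.null(names(condition_scales)))
    stop("`condition_scales` must be named by condition", call. = FALSE)
  if (!"none" %in% names(condition_scales) || condition_scales[["none"]] != 1)
    stop("the baseline condition 'none' must be present with scale 1", call. = FALSE)
  if (carrier_band[1] <= 0 || carrier_band[2] >= fs / 2 ||
      carrier_band[2] <= carrier_band[1])
    stop("`carrier_band` must lie within (0, fs/2)", call. = FALSE)
  structure(list(n_reps = n_reps, burst_duration = burst_duration,
                 inter_burst = inter_burst, fs = fs,
                 base_envelope = base_envelope,
                 condition_scales = condition_scales,
                 carrier_band = carrier_band, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "semg_config")
}

# Band-limited unit-variance Gaussian noise via FFT masking.
bandlimited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided -> folded frequency
  W[freq < band[1] | freq > band[2]] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a surrogate sEMG record
#'
#' @param cfg A [semg_config()].
#' @param condition Condition label; must be a name of
#'   `cfg$condition_scales`.
#' @param muscle,subject Labels stored on the record.
#' @return An [emg_record()], zero-mean, deterministic given
#'   `cfg$seed` (records for different conditions share the seed so the
#'   carrier is common and only the envelope scale differs).
#' @export
gen_semg <- function(cfg, condition = "none", muscle = "FCU", subject = "S1") {
  if (!inherits(cfg, "semg_config"))
    stop("`cfg` must be created with semg_config()", call. = FALSE)
  if (!condition %in% names(cfg$condition_scales))
    stop(sprintf("unknown condition '%s'", condition), call. = FALSE)
  period <- cfg$burst_duration + cfg$inter_burst
  dur <- cfg$n_reps * period
  n <- round(dur * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  env <- numeric(n)
  for (i in seq_len(cfg$n_reps)) {
    t0 <- (i - 1) * period
    inb <- t >= t0 & t < t0 + cfg$burst_duration
    env[inb] <- (1 - cos(2 * pi * (t[inb] - t0) / cfg$burst_duration)) / 2
  }
  scale <- cfg$condition_scales[[condition]]
  v <- with_seed(cfg$seed, {
    carrier <- bandlimited_noise(n, cfg$fs, cfg$carrier_band)
    noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else 0
    cfg$base_envelope * scale * env * carrier + noise
  })
  v <- v - mean(v)
  emg_record(t, v, fs = cfg$fs, muscle = muscle, condition = condition,
             subject = subject)
}

#' Write the canonical synthetic fixture bundle
#'
#' Generates the CSV fixtures used by the documentation and integration
#' tests: wrist F/E and R/U traces spanning the anatomical ROM, the four
#' elbow/shoulder half-compliant counting protocols, and surrogate sEMG for
#' three subjects, three resistance conditions and two motion patterns. A
#' `manifest.csv` lists every file with its generator parameters.
#'
#' @param dir Output directory (created if absent).
#' @param seed Integer master seed; per-file seeds are derived from it, so
#'   a fixed seed reproduces the bundle byte for byte.
#' @return Invisibly, the manifest data.frame.
#' @export
gen_fixture_suite <- function(dir, seed = 1L) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      stop("cannot create output directory", call. = FALSE)
  seed <- as.integer(seed)
  manifest <- list()
  add <- function(file, kind, params) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, kind = kind, params = params, stringsAsFactors = FALSE)
  }

  # wrist traces covering the anatomical ROM (extension/ulnar positive)
  wrist_cfgs <- list(
    fe = angle_trace_config("fe", per_rep_amplitudes = rep(70, 5),
                            noise_sd = 0.5, joint = "wrist", seed = seed + 11L),
    ru = angle_trace_config("ru", per_rep_amplitudes = rep(35, 5),
                            noise_sd = 0.5, joint = "wrist", seed = seed + 12L))
  for (p in names(wrist_cfgs)) {
    ser <- gen_angle_trace(wrist_cfgs[[p]])
    f <- file.path(dir, sprintf("wrist_%s.csv", p))
    write_timeseries_csv(f, ser$t, ser$angle, c("t", "angle"))
    add(basename(f), "angle",
        sprintf("joint=wrist pattern=%s reps=5 seed=%d", p, wrist_cfgs[[p]]$seed))
  }

  # elbow/shoulder half-compliant counting protocols
  for (p in names(default_thresholds())) {
    cfg <- counting_protocol_config(p, seed = seed + 20L + match(p, names(default_thresholds())))
    ser <- gen_angle_trace(cfg)
    f <- file.path(dir, sprintf("%s_protocol.csv", p))
    write_timeseries_csv(f, ser$t, ser$angle, c("t", "angle"))
    add(basename(f), "angle",
        sprintf("pattern=%s reps=10 compliant=5 seed=%d", p, cfg$seed))
  }

  # surrogate sEMG: 3 subjects x 2 patterns x 3 conditions
  muscles <- c(fe = "FCU", ru = "FCR")
  for (s in 1:3) {
    for (p in c("fe", "ru")) {
      cfg <- semg_config(seed = seed + 100L * s + match(p, c("fe", "ru")))
      for (cond in names(cfg$condition_scales)) {
        rec <- gen_semg(cfg, cond, muscle = muscles[[p]],
                        subject = sprintf("S%d", s))
        f <- file.path(dir, sprintf("emg_S%d_%s_%s.csv", s, p, cond))
        write_timeseries_csv(f, rec$t, rec$v, c("t", "v"))
        add(basename(f), "emg",
            sprintf("subject=S%d pattern=%s condition=%s seed=%d",
                    s, p, cond, cfg$seed))
      }
    }
  }

  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
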