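#' Uniformly sampled joint-angle trace
#'
#' Container for a single-joint angle time series recorded by the wearable
#' orthosis' posture sensors. Angles are in degrees with the neutral
#' position at zero; extension and ulnar deviation are the positive
#' directions.
#'
#' @param t Time stamps (s), uniformly spaced.
#' @param angle Joint angle (degrees), same length as `t`.
#' @param joint Joint label: `"wrist"`, `"elbow"` or `"shoulder"`.
#' @param pattern Motion-pattern label (e.g. `"fe"`, `"ru"`, `"abd_add"`,
#'   `"rot"`).
#' @param fs Sampling rate (Hz); inferred from `t` when `NULL`.
#' @param jitter_tol Maximum tolerated relative deviation of sample
#'   intervals from uniformity.
#' @return An object of class `joint_angle_series`.
#' @export
joint_angle_series <- function(t, angle, joint = "wrist", pattern = "fe",
                               fs = NULL, jitter_tol = 1e-6) {
  if (length(t) != length(angle))
    stop("`t` and `angle` must have equal length", call. = FALSE)
  if (length(t) < 2L) stop("series needs at least two samples", call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(angle)))
    stop("time stamps and angles must be finite", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing", call. = FALSE)
  if (max(abs(dt - mean(dt))) > jitter_tol * mean(dt))
    stop("non-uniform sampling: interval jitter exceeds tolerance", call. = FALSE)
  if (is.null(fs)) fs <- 1 / mean(dt)
  structure(list(t = as.numeric(t), angle = as.numeric(angle),
                 joint = joint, pattern = pattern, fs = fs),
            class = "joint_angle_series")
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("joint-angle series: %s %s, %d samples @ %g Hz, range [%.1f, %.1f] deg\n",
              x$joint, x$pattern, length(x$t), x$fs,
              min(x$angle), max(x$angle)))
  invisible(x)
}

as_joint_angle_series <- function(series) {
  if (!inherits(series, "joint_angle_series"))
    stop("`series` must be created with joint_angle_series()", call. = FALSE)
  series
}

#' Repetition-counting threshold pair
#'
#' A complete training action is one that rises above `upper` and
#' subsequently falls below `lower` (hysteresis, so oscillation around a
#' single level cannot double-count). Negative lower thresholds describe
#' reciprocating patterns whose return phase must overshoot past the
#' opposite side.
#'
#' @param upper,lower Thresholds in degrees, `upper > lower`.
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(upper, lower) {
  stopifnot_scalar(upper, "upper")
  stopifnot_scalar(lower, "lower")
  if (upper <= lower) stop("`upper` must exceed `lower`", call. = FALSE)
  structure(list(upper = upper, lower = lower), class = "threshold_pair")
}

#' Default elbow/shoulder monitoring thresholds
#'
#' The threshold pairs used by the fixation device's training monitor:
#' elbow flexion/extension (45, 30), elbow abduction/adduction (30, -30),
#' shoulder flexion/extension (30, -30), shoulder internal/external
#' rotation (45, 30).
#'
#' @return Named list of [threshold_pair()] objects with names
#'   `elbow_fe`, `elbow_abd_add`, `shoulder_fe`, `shoulder_rot`.
#' @export
default_thresholds <- function() {
  list(elbow_fe      = threshold_pair(45, 30),
       elbow_abd_add = threshold_pair(30, -30),
       shoulder_fe   = threshold_pair(30, -30),
       shoulder_rot  = threshold_pair(45, 30))
}

#' Anatomical and functional wrist range-of-motion limits
#'
#' Anatomical limits: flexion 75, extension 70, radial 20, ulnar 35
#' degrees. Functional limits — the minimum ranges needed to perform
#' activities of daily living comfortably: flexion 40, extension 40,
#' radial 10, ulnar 20 degrees.
#'
#' @return List with numeric vectors `anatomical` and `functional`, each
#'   named `flexion`, `extension`, `radial`, `ulnar`.
#' @export
rom_limits <- function() {
  list(anatomical = c(flexion = 75, extension = 70, radial = 20, ulnar = 35),
       functional = c(flexion = 40, extension = 40, radial = 10, ulnar = 20))
}

#' Count complete repetitions with a hysteresis threshold pair
#'
#' Walks the trace with a two-state machine: the counter arms when the
#' angle rises strictly above `upper`, registers one repetition when the
#' armed trace falls strictly below `lower`, then resets. The count can
#' therefore never exceed the number of upward crossings of `upper`, and is
#' invariant to resampling that preserves the crossing structure.
#'
#' @param series A [joint_angle_series()].
#' @param thr A [threshold_pair()].
#' @param min_duration Minimum time (s) between arming and registration for
#'   a repetition to count; 0 disables the check.
#' @return Integer repetition count.
#' @export
count_reps <- function(series, thr, min_duration = 0) {
  series <- as_joint_angle_series(series)
  if (!inherits(thr, "threshold_pair"))
    stop("`thr` must be created with threshold_pair()", call. = FALSE)
  armed <- FALSE
  armed_at <- NA_real_
  n <- 0L
  for (i in seq_along(series$angle)) {
    a <- series$angle[i]
    if (!armed && a > thr$upper) {
      armed <- TRUE
      armed_at <- series$t[i]
    } else if (armed && a < thr$lower) {
      if (series$t[i] - armed_at >= min_duration) n <- n + 1L
      armed <- FALSE
    }
  }
  n
}

#' Range of motion and per-repetition excursions of a trace
#'
#' Global minimum/maximum plus per-repetition peak excursions. Repetitions
#' are segmented at upward crossings of the lower threshold when `thr` is
#' given, otherwise at upward zero crossings with a small hysteresis
#' deadband (`hysteresis`, degrees) so sensor noise near zero does not
#' split segments.
#'
#' @param series A [joint_angle_series()].
#' @param thr Optional [threshold_pair()]; its `lower` value becomes the
#'   segmentation level.
#' @param hysteresis Deadband half-width (degrees) for zero-crossing
#'   segmentation.
#' @return List with `min`, `max` (degrees) and `reps`, a data.frame with
#'   one row per segment (`start_s`, `end_s`, `peak_deg`, `trough_deg`).
#' @export
extract_rom <- function(series, thr = NULL, hysteresis = 3) {
  series <- as_joint_angle_series(series)
  a <- series$angle
  level <- if (is.null(thr)) 0 else thr$lower
  hi <- level + if (is.null(thr)) hysteresis else 0
  lo <- level - if (is.null(thr)) hysteresis else 0
  # state: TRUE once above hi, reset once below lo; segment = one TRUE span
  starts <- integer(0); ends <- integer(0)
  up <- FALSE; seg_start <- NA_integer_
  for (i in seq_along(a)) {
    if (!up && a[i] > hi) {
      up <- TRUE; seg_start <- i
    } else if (up && a[i] < lo) {
      up <- FALSE
      starts <- c(starts, seg_start); ends <- c(ends, i)
    }
  }
  # a segment still open at the end of the trace never returned below the
  # segmentation level and is not a completed repetition
  reps <- data.frame(start_s = series$t[starts], end_s = series$t[ends],
                     peak_deg = vapply(seq_along(starts), function(j)
                       max(a[starts[j]:ends[j]]), numeric(1)),
                     trough_deg = vapply(seq_along(starts), function(j)
                       min(a[starts[j]:ends[j]]), numeric(1)))
  list(min = min(a), max = max(a), reps = reps)
}

#' Functional range-of-motion compliance of a wrist trace
#'
#' Checks whether the measured excursions cover the functional ROM in each
#' direction of the pattern's axis: flexion and extension both need 40
#' degrees for the F/E pattern; radial 10 and ulnar 20 degrees for the R/U
#' pattern. Extension/ulnar are the positive trace directions.
#'
#' @param rom Result of [extract_rom()] (or any list with `min` and `max`
#'   in degrees).
#' @param pattern `"fe"` or `"ru"`.
#' @return Named logical vector, one element per direction.
#' @export
check_functional_rom <- function(rom, pattern = c("fe", "ru")) {
  pattern <- match.arg(pattern)
  fun <- rom_limits()$functional
  if (pattern == "fe")
    c(flexion = -rom$min >= fun[["flexion"]],
      extension = rom$max >= fun[["extension"]])
  else
    c(radial = -rom$min >= fun[["radial"]],
      ulnar = rom$max >= fun[["ulnar"]])
}

# Intrinsic Z-Y-X Euler triplet (deg) -> rotation matrix.
euler_zyx_to_matrix <- function(e) {
  y <- deg2rad(e[1]); p <- deg2rad(e[2]); r <- deg2rad(e[3])
  Rz <- matrix(c(cos(y), -sin(y), 0, sin(y), cos(y), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cos(p), 0, sin(p), 0, 1, 0, -sin(p), 0, cos(p)), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cos(r), -sin(r), 0, sin(r), cos(r)), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Joint angle from two segment orientations
#'
#' Computes the relative rotation hand-relative-to-forearm from the two
#' posture sensors' intrinsic Z-Y-X Euler triplets and returns its Euler
#' component about the requested axis: `"z"` (yaw), `"y"` (pitch) or `"x"`
#' (roll). When the relative pitch is within `gimbal_tol` of +/-90 degrees
#' the yaw/roll split is degenerate and the result carries
#' `attr(, "gimbal") = TRUE`.
#'
#' @param hand_orientation,forearm_orientation Numeric length-3 Euler
#'   triplets (degrees), intrinsic Z-Y-X, in a shared fixed reference frame.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param gimbal_tol Degeneracy tolerance on `|cos(pitch)|`.
#' @return Joint angle (degrees) with attribute `gimbal`.
#' @export
relative_joint_angle <- function(hand_orientation, forearm_orientation,
                                 axis = c("y", "z", "x"), gimbal_tol = 1e-6) {
  axis <- match.arg(axis)
  Rh <- euler_zyx_to_matrix(hand_orientation)
  Rf <- euler_zyx_to_matrix(forearm_orientation)
  Rrel <- crossprod(Rf, Rh)      # forearm^T %*% hand
  # decompose Rrel = Rz(yaw) Ry(pitch) Rx(roll)
  sp <- -Rrel[3, 1]
  sp <- min(1, max(-1, sp))
  pitch <- asin(sp)
  gimbal <- abs(cos(pitch)) < gimbal_tol
  if (gimbal) {
    yaw <- atan2(-Rrel[1, 2], Rrel[2, 2])
    roll <- 0
  } else {
    yaw <- atan2(Rrel[2, 1], Rrel[1, 1])
    roll <- atan2(Rrel[3, 2], Rrel[3, 3])
  }
  out <- rad2deg(switch(axis, z = yaw, y = pitch, x = roll))
  attr(out, "gimbal") <- gimbal
  out
}
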