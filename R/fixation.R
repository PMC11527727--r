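#' Mechanical state of a reduced distal-radius fracture end
#'
#' Bundles the scalar quantities entering the friction statics of the
#' fracture line: the contact force `N` pressing the two fracture surfaces
#' together, the equivalent external-fixation force `G` supplied by an
#' orthosis, the inter-surface friction coefficient `f`, and the inclination
#' `alpha` of the fracture line. All forces are magnitudes; the analysis is
#' scalar along/across the fracture plane.
#'
#' @param N Contact-force magnitude between the fracture surfaces (N, >= 0).
#' @param f Friction coefficient between the fracture surfaces (>= 0).
#' @param alpha_deg Inclined angle of the fracture line in degrees,
#'   `0 <= alpha < 90`. Stored internally in radians.
#' @param G Equivalent external-fixation force magnitude (N, >= 0).
#'   Defaults to 0 (no fixation).
#' @return An object of class `fixation_state`.
#' @examples
#' st <- fixation_state(N = 10, f = 0.3, alpha_deg = 25, G = 1)
#' is_stable_fixed(st)
#' @export
fixation_state <- function(N, f, alpha_deg, G = 0) {
  stopifnot_scalar(N, "N", nonneg = TRUE)
  stopifnot_scalar(G, "G", nonneg = TRUE)
  stopifnot_scalar(f, "f", nonneg = TRUE)
  stopifnot_scalar(alpha_deg, "alpha_deg")
  if (alpha_deg < 0 || alpha_deg >= 90)
    stop("`alpha_deg` must lie in [0, 90)", call. = FALSE)
  structure(
    list(N = N, G = G, f = f, alpha = deg2rad(alpha_deg)),
    class = "fixation_state"
  )
}

#' @export
print.fixation_state <- function(x, ...) {
  cat(sprintf(
    "fracture fixation state: N = %g N, G = %g N, f = %g, alpha = %g deg\n",
    x$N, x$G, x$f, rad2deg(x$alpha)))
  invisible(x)
}

as_fixation_state <- function(state) {
  if (!inherits(state, "fixation_state"))
    stop("`state` must be created with fixation_state()", call. = FALSE)
  state
}

#' Decompose the contact force along and across the fracture line
#'
#' Splits the inter-fragment contact force into its component normal to the
#' fracture plane (`N cos(alpha)`, which generates friction) and the
#' tangential component along the plane (`N sin(alpha)`, which drives
#' displacement).
#'
#' @param state A [fixation_state()].
#' @return Named numeric vector with components `normal` and `tangential` (N).
#' @export
decompose_contact_force <- function(state) {
  state <- as_fixation_state(state)
  c(normal = state$N * cos(state$alpha),
    tangential = state$N * sin(state$alpha))
}

#' Stability of the unfixed fracture end
#'
#' Without external fixation the fragment holds its position only if the
#' tangential drive does not exceed the available friction:
#' `N sin(alpha) <= f N cos(alpha)`, i.e. `tan(alpha) <= f`.
#'
#' @inheritParams decompose_contact_force
#' @return `TRUE` if the fracture end is stable without fixation.
#' @export
is_stable_unfixed <- function(state) {
  state <- as_fixation_state(state)
  tan(state$alpha) <= state$f
}

#' Stability of the fracture end under external fixation
#'
#' The fixation force `G` adds `G sin(alpha)` to the normal (friction-
#' generating) load and subtracts `G cos(alpha)` from the tangential drive,
#' so the stability condition becomes
#' `N sin(alpha) - G cos(alpha) <= f (N cos(alpha) + G sin(alpha))`.
#' With `G = 0` this reduces to [is_stable_unfixed()].
#'
#' @inheritParams decompose_contact_force
#' @return `TRUE` if the fixed fracture end is stable.
#' @export
is_stable_fixed <- function(state) {
  state <- as_fixation_state(state)
  sa <- sin(state$alpha); ca <- cos(state$alpha)
  state$N * sa - state$G * ca <= state$f * (state$N * ca + state$G * sa)
}

#' Largest stable fracture-line inclination under fixation
#'
#' Solves the fixed-stability inequality for the angle, giving
#' `tan(alpha_max) = (f N + G) / (N - f G)` whenever `N - f G > 0`.
#' `alpha_max` is always at least the friction angle `atan(f)`: fixation can
#' only enlarge the stable range. When `N - f G <= 0` the inequality holds
#' for every inclination below 90 degrees and the result is tagged unbounded.
#'
#' @inheritParams decompose_contact_force
#' @param degrees Return the angle in degrees (default) or radians.
#' @return A list with `angle` (numeric; `90` / `pi/2` in the unbounded
#'   regime) and `bounded` (logical; `FALSE` when `N - f G <= 0`).
#' @export
max_stable_angle <- function(state, degrees = TRUE) {
  state <- as_fixation_state(state)
  denom <- state$N - state$f * state$G
  if (denom <= 0) {
    ang <- if (degrees) 90 else pi / 2
    return(list(angle = ang, bounded = FALSE))
  }
  a <- atan((state$f * state$N + state$G) / denom)
  list(angle = if (degrees) rad2deg(a) else a, bounded = TRUE)
}
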