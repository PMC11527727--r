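#' Parameters of the planar spring-resisted wrist model
#'
#' Geometry, inertia and spring stiffness of the single-degree-of-freedom
#' sagittal-plane model of wrist rotation: the forearm lies along the x axis,
#' the wrist joint sits at its distal end, and the hand rotates about the
#' joint by the angle `theta` (extension positive). A linear extension spring
#' connects an anchor on the hand (distance `l3` from the joint) to an anchor
#' on the forearm (offset `l4` from the forearm axis); at `theta = 0` the
#' spring is at its natural length.
#'
#' @param m Hand mass (kg).
#' @param d Distance from the wrist joint to the hand centroid (m).
#' @param l1 Forearm length (m).
#' @param l3 Distance from the wrist joint to the hand-side spring anchor (m).
#' @param l4 Offset of the forearm-side spring anchor from the forearm axis (m).
#' @param k Spring stiffness (N/m); `k = 0` recovers the free (unresisted)
#'   model.
#' @param g Gravitational acceleration (m/s^2).
#' @param l2 Hand length (m); carried as metadata, not used by the dynamics.
#' @return An object of class `wrist_params`.
#' @details The default parameter set (0.4 kg hand, 8 cm centroid distance,
#'   25 cm forearm, 5 cm / 3 cm anchors) is an anthropometrically plausible
#'   adult configuration used by the package's examples and tests.
#' @export
wrist_params <- function(m = 0.4, d = 0.08, l1 = 0.25, l3 = 0.05, l4 = 0.03,
                         k = 0, g = 9.81, l2 = NULL) {
  stopifnot_scalar(m, "m", positive = TRUE)
  stopifnot_scalar(d, "d", positive = TRUE)
  stopifnot_scalar(l1, "l1", positive = TRUE)
  stopifnot_scalar(l3, "l3", nonneg = TRUE)
  stopifnot_scalar(l4, "l4", nonneg = TRUE)
  stopifnot_scalar(k, "k", nonneg = TRUE)
  stopifnot_scalar(g, "g", nonneg = TRUE)
  structure(list(m = m, d = d, l1 = l1, l3 = l3, l4 = l4, k = k, g = g,
                 l2 = l2),
            class = "wrist_params")
}

#' @export
print.wrist_params <- function(x, ...) {
  cat(sprintf(
    "planar wrist model: m = %g kg, d = %g m, l1 = %g m, l3 = %g m, l4 = %g m, k = %g N/m\n",
    x$m, x$d, x$l1, x$l3, x$l4, x$k))
  invisible(x)
}

as_wrist_params <- function(params) {
  if (!inherits(params, "wrist_params"))
    stop("`params` must be created with wrist_params()", call. = FALSE)
  params
}

#' Hand centroid position and speed
#'
#' The hand centroid sits at `(l1 + d cos(theta), d sin(theta))` in the
#' forearm frame and moves on a circle of radius `d`, so its speed is
#' `|d * theta_dot|`.
#'
#' @param params A [wrist_params()].
#' @param theta Wrist angle (rad).
#' @param theta_dot Wrist angular velocity (rad/s).
#' @return List with `position` (2-vector, m) and `speed` (m/s).
#' @export
hand_kinematics <- function(params, theta, theta_dot = 0) {
  params <- as_wrist_params(params)
  list(position = c(params$l1 + params$d * cos(theta),
                    params$d * sin(theta)),
       speed = abs(params$d * theta_dot))
}

#' Spring elongation of the planar resistance module
#'
#' Distance between the hand anchor `(l1 - l3 sin(theta), l3 cos(theta))`
#' and the forearm anchor `(0, l4)`, minus the anchor distance at the
#' neutral pose, giving
#' `sqrt(l1^2 + l3^2 + l4^2 - 2 l1 l3 sin(theta) - 2 l3 l4 cos(theta)) -
#'  sqrt(l1^2 + (l3 - l4)^2)`.
#' Zero at `theta = 0` and identically zero when the hand anchor sits on the
#' joint axis (`l3 = 0`).
#'
#' @inheritParams hand_kinematics
#' @param theta Wrist angle (rad); vectorised.
#' @return Elongation (m), same length as `theta`.
#' @export
spring_elongation_planar <- function(params, theta) {
  params <- as_wrist_params(params)
  rad <- params$l1^2 + params$l3^2 + params$l4^2 -
    2 * params$l1 * params$l3 * sin(theta) -
    2 * params$l3 * params$l4 * cos(theta)
  if (any(rad < 0))
    stop("negative radicand: geometrically impossible parameters", call. = FALSE)
  sqrt(rad) - sqrt(params$l1^2 + (params$l3 - params$l4)^2)
}

# dDx/dtheta by the chain rule; used by the resisted torque.
spring_elongation_deriv <- function(params, theta) {
  rad <- params$l1^2 + params$l3^2 + params$l4^2 -
    2 * params$l1 * params$l3 * sin(theta) -
    2 * params$l3 * params$l4 * cos(theta)
  (-params$l1 * params$l3 * cos(theta) + params$l3 * params$l4 * sin(theta)) /
    sqrt(rad)
}

#' Mechanical energies of the wrist-hand system
#'
#' Kinetic energy `Ek = m d^2 theta_dot^2 / 2`, gravitational potential
#' `Ep1 = m g d sin(theta)` (zero at the neutral pose), and elastic
#' potential of the resistance spring `Ep2 = k Dx(theta)^2 / 2`.
#'
#' @inheritParams hand_kinematics
#' @return Named numeric vector `c(Ek, Ep1, Ep2)` in joules.
#' @export
wrist_energies <- function(params, theta, theta_dot = 0) {
  params <- as_wrist_params(params)
  dx <- spring_elongation_planar(params, theta)
  c(Ek = 0.5 * params$m * params$d^2 * theta_dot^2,
    Ep1 = params$m * params$g * params$d * sin(theta),
    Ep2 = 0.5 * params$k * dx^2)
}

#' Wrist joint torque without resistance
#'
#' Lagrangian torque of the free (spring-less) model:
#' `T1 = m d^2 theta_ddot + m g d cos(theta)`. At rest in the neutral pose
#' this is the gravity-holding torque `m g d`; with the hand vertical
#' (`theta = 90` degrees) it vanishes.
#'
#' @inheritParams hand_kinematics
#' @param theta_ddot Wrist angular acceleration (rad/s^2).
#' @return Torque T1 (N m).
#' @export
free_torque <- function(params, theta, theta_ddot = 0) {
  params <- as_wrist_params(params)
  params$m * params$d^2 * theta_ddot +
    params$m * params$g * params$d * cos(theta)
}

#' Wrist joint torque with the spring resistance module
#'
#' Adding the elastic potential to the Lagrangian contributes the extra
#' torque `Te = k Dx(theta) dDx/dtheta`, so the total joint torque is
#' `T2 = T1 + Te` identically. `k = 0` gives `Te = 0`.
#'
#' @inheritParams free_torque
#' @return Named numeric vector `c(T1, Te, T2)` (N m).
#' @export
resisted_torque <- function(params, theta, theta_ddot = 0) {
  params <- as_wrist_params(params)
  t1 <- free_torque(params, theta, theta_ddot)
  te <- params$k * spring_elongation_planar(params, theta) *
    spring_elongation_deriv(params, theta)
  c(T1 = t1, Te = te, T2 = t1 + te)
}

#' Static torque profile over a wrist-angle sweep
#'
#' Evaluates the free and resisted joint torques over a grid of wrist
#' angles (quasi-static, `theta_ddot = 0`).
#'
#' @inheritParams hand_kinematics
#' @param theta_deg_range Length-2 numeric, sweep limits in degrees.
#' @param by_deg Grid step in degrees.
#' @return A data.frame with columns `theta_deg`, `elongation_m`, `T1`,
#'   `Te`, `T2`.
#' @export
torque_profile <- function(params, theta_deg_range = c(-75, 70), by_deg = 1) {
  params <- as_wrist_params(params)
  th_deg <- seq(theta_deg_range[1], theta_deg_range[2], by = by_deg)
  th <- deg2rad(th_deg)
  t1 <- free_torque(params, th)
  dx <- spring_elongation_planar(params, th)
  te <- params$k * dx * spring_elongation_deriv(params, th)
  data.frame(theta_deg = th_deg, elongation_m = dx,
             T1 = t1, Te = te, T2 = t1 + te)
}
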