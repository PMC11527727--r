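#' Extension-spring physical specification and stiffness
#'
#' Standard helical extension-spring rate
#' `k = G d^4 / (8 n D^3)` from the shear modulus `G`, wire diameter `d`,
#' mean coil diameter `D` and number of active coils `n`. Inputs are taken
#' in the units springs are catalogued in (GPa and mm); the returned rate is
#' in N/m.
#'
#' @param G_shear Shear modulus (GPa).
#' @param D_mean Mean coil diameter (mm).
#' @param d_wire Wire diameter (mm).
#' @param n_coils Number of active coils.
#' @return An object of class `spring_spec`.
#' @examples
#' spring_constant(spring_spec(d_wire = 0.8))  # 409.6 N/m
#' spring_constant(spring_spec(d_wire = 1.0))  # 1000  N/m
#' @export
spring_spec <- function(G_shear = 200, D_mean = 10, d_wire = 0.8, n_coils = 25) {
  for (nm in c("G_shear", "D_mean", "d_wire", "n_coils"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  structure(list(G_shear = G_shear, D_mean = D_mean, d_wire = d_wire,
                 n_coils = n_coils),
            class = "spring_spec")
}

#' @rdname spring_spec
#' @param spec A `spring_spec`.
#' @return `spring_constant()`: stiffness in N/m.
#' @export
spring_constant <- function(spec) {
  if (!inherits(spec, "spring_spec"))
    stop("`spec` must be created with spring_spec()", call. = FALSE)
  G <- spec$G_shear * 1e9      # GPa -> Pa
  d <- spec$d_wire * 1e-3      # mm  -> m
  D <- spec$D_mean * 1e-3
  G * d^4 / (8 * spec$n_coils * D^3)
}

#' Modified Denavit-Hartenberg link transform
#'
#' Homogeneous transform between consecutive frames in the modified D-H
#' convention (link parameters attached to the preceding link):
#' a rotation `alpha_prev` about x, translation `a_prev` along x, rotation
#' `theta` about the new z, translation `d_i` along z. The joint variable is
#' `joint_angle + theta_offset`.
#'
#' @param a_prev Link length (mm).
#' @param alpha_prev Link twist (rad).
#' @param d_i Link offset (mm).
#' @param theta_offset Constant added to the joint variable (rad).
#' @param joint_angle Joint variable (rad).
#' @return 4x4 homogeneous transform (translations in mm).
#' @export
dh_transform <- function(joint_angle, a_prev = 0, alpha_prev = 0, d_i = 0,
                         theta_offset = 0) {
  th <- joint_angle + theta_offset
  ct <- cos(th); st <- sin(th)
  ca <- cos(alpha_prev); sa <- sin(alpha_prev)
  matrix(c(
    ct,      -st,       0,    a_prev,
    st * ca,  ct * ca, -sa,  -sa * d_i,
    st * sa,  ct * sa,  ca,   ca * d_i,
    0,        0,        0,    1
  ), nrow = 4, byrow = TRUE)
}

#' The two-joint D-H table of the resistance training device
#'
#' Wrist flexion/extension (`theta1`, about the base z axis) followed by
#' radial/ulnar deviation (`theta2`), with link twist `-pi/2` and constant
#' joint offset `-pi/2` on the second row. All link lengths and offsets are
#' zero: the two anatomical axes are modelled as intersecting at the wrist
#' centre.
#'
#' @return A data.frame with columns `a_prev` (mm), `alpha_prev` (rad),
#'   `d_i` (mm), `theta_offset` (rad); one row per joint.
#' @export
rtd_dh_table <- function() {
  data.frame(a_prev = c(0, 0),
             alpha_prev = c(0, -pi / 2),
             d_i = c(0, 0),
             theta_offset = c(0, -pi / 2))
}

#' Forearm-to-hand transform of the 2-DOF wrist
#'
#' Product of the two D-H row transforms of [rtd_dh_table()], equal to the
#' closed form
#' \preformatted{
#'   [ c1 s2   c1 c2   -s1   0 ]
#'   [ s1 s2   s1 c2    c1   0 ]
#'   [   c2     -s2      0   0 ]
#'   [    0       0      0   1 ]
#' }
#' with `c1 = cos(theta1)` etc.
#'
#' @param theta1 Flexion/extension angle (rad); flexion negative.
#' @param theta2 Radial/ulnar deviation angle (rad); radial positive.
#' @param closed_form Use the closed form (default) or the explicit product
#'   of the two [dh_transform()] rows (identical to machine precision).
#' @return 4x4 homogeneous transform.
#' @export
wrist_transform <- function(theta1, theta2, closed_form = TRUE) {
  if (!closed_form) {
    tab <- rtd_dh_table()
    t01 <- dh_transform(theta1, tab$a_prev[1], tab$alpha_prev[1],
                        tab$d_i[1], tab$theta_offset[1])
    t12 <- dh_transform(theta2, tab$a_prev[2], tab$alpha_prev[2],
                        tab$d_i[2], tab$theta_offset[2])
    return(t01 %*% t12)
  }
  c1 <- cos(theta1); s1 <- sin(theta1)
  c2 <- cos(theta2); s2 <- sin(theta2)
  matrix(c(
    c1 * s2, c1 * c2, -s1, 0,
    s1 * s2, s1 * c2,  c1, 0,
    c2,     -s2,        0, 0,
    0,       0,         0, 1
  ), nrow = 4, byrow = TRUE)
}

# Default rope-spring kit anchors (mm, base frame {0}, neutral pose).
# Rows = kits 1..4; pulley outlets A on the forearm, rope ends B on the hand.
.kit_A_default <- matrix(c(-12, 40, 12,
                           -12, 40, -12,
                           -12, -40, 12,
                           -12, -40, -12), nrow = 4, byrow = TRUE)
.kit_B_default <- matrix(c(42, 12.5, 12,
                           42, 12.5, -12,
                           42, -12.5, 12,
                           42, -12.5, -12), nrow = 4, byrow = TRUE)

#' Rope-spring kit anchor geometry
#'
#' Each of the four rope-spring kits runs from a pulley outlet `A` on the
#' forearm module to a rope end `B` on the hand module. Kits 1 and 2 sit on
#' the palmar side (positive y) and are tensioned by flexion; kits 3 and 4
#' sit dorsally and are tensioned by extension; kits 1 and 3 share the
#' radial side, kits 2 and 4 the ulnar side.
#'
#' @param kit_id Kit number, 1-4.
#' @param A Pulley-outlet point, 3-vector (mm). By default the built-in
#'   device geometry for `kit_id`.
#' @param B Hand-anchor point, 3-vector (mm); interpreted according to
#'   `b_frame`.
#' @param b_frame Frame in which `B` is given: `"base"` (default) means `B`
#'   is the anchor's position in the base frame at the neutral pose and is
#'   mapped into the hand frame internally; `"hand"` means `B` is already a
#'   hand-frame coordinate.
#' @return An object of class `kit_geometry` with `A` (base frame) and
#'   `B_hand` (hand frame).
#' @export
kit_geometry <- function(kit_id = 1, A = NULL, B = NULL,
                         b_frame = c("base", "hand")) {
  b_frame <- match.arg(b_frame)
  if (!kit_id %in% 1:4) stop("`kit_id` must be 1, 2, 3 or 4", call. = FALSE)
  if (is.null(A)) A <- .kit_A_default[kit_id, ]
  if (is.null(B)) B <- .kit_B_default[kit_id, ]
  if (length(A) != 3 || length(B) != 3 || !is.numeric(A) || !is.numeric(B))
    stop("`A` and `B` must be numeric 3-vectors", call. = FALSE)
  R0 <- wrist_transform(0, 0)[1:3, 1:3]
  B_hand <- if (b_frame == "base") drop(crossprod(R0, B)) else as.numeric(B)
  structure(list(kit_id = kit_id, A = as.numeric(A), B_hand = B_hand),
            class = "kit_geometry")
}

#' Spring elongation of one rope-spring kit at a wrist pose
#'
#' Maps the hand anchor into the base frame through the wrist transform,
#' takes the straight-line distance to the pulley outlet, and subtracts the
#' neutral-pose distance. Zero at the neutral pose; negative values mean the
#' rope has slackened (the kit is bent out of action and transmits no
#' force).
#'
#' @param kit A [kit_geometry()].
#' @param theta1,theta2 Wrist pose (rad); vectorised over equal lengths.
#' @return Elongation (mm).
#' @export
kit_elongation <- function(kit, theta1, theta2) {
  if (!inherits(kit, "kit_geometry"))
    stop("`kit` must be created with kit_geometry()", call. = FALSE)
  n <- max(length(theta1), length(theta2))
  theta1 <- rep_len(theta1, n); theta2 <- rep_len(theta2, n)
  d0 <- {
    b0 <- wrist_transform(0, 0)[1:3, 1:3] %*% kit$B_hand
    sqrt(sum((b0 - kit$A)^2))
  }
  vapply(seq_len(n), function(i) {
    b <- wrist_transform(theta1[i], theta2[i])[1:3, 1:3] %*% kit$B_hand
    sqrt(sum((b - kit$A)^2)) - d0
  }, numeric(1))
}

#' Elongation surface of a kit over the wrist range of motion
#'
#' @param kit A [kit_geometry()].
#' @param theta1_deg,theta2_deg Grid vectors in degrees.
#' @return Matrix of elongations (mm), rows indexed by `theta1_deg`, columns
#'   by `theta2_deg`, with dimnames set to the grid values.
#' @export
elongation_map <- function(kit, theta1_deg = seq(-75, 70, by = 1),
                           theta2_deg = seq(-35, 20, by = 1)) {
  m <- outer(deg2rad(theta1_deg), deg2rad(theta2_deg),
             function(t1, t2) kit_elongation(kit, t1, t2))
  dimnames(m) <- list(theta1_deg, theta2_deg)
  m
}

#' Resistance force of a tensioned kit pair
#'
#' Two kits of equal stiffness act in parallel on each motion pattern, so
#' `F = 2 k x` for elongation `x >= 0`. A slack rope (negative elongation)
#' transmits no force.
#'
#' @param k Spring stiffness (N/m).
#' @param x Spring elongation (m); clamped below at zero.
#' @return Force (N).
#' @export
group_force <- function(k, x) 2 * k * pmax(x, 0)

# Per-pattern tensioned kit pairs and the signed single-axis ROM extreme
# (deg). theta2 positive is radial so that kits 1 and 3 are the radially
# tensioned pair.
.rtd_patterns <- list(
  flexion   = list(kits = c(1, 2), axis = 1, extreme = -75),
  extension = list(kits = c(3, 4), axis = 1, extreme = 70),
  radial    = list(kits = c(1, 3), axis = 2, extreme = 20),
  ulnar     = list(kits = c(2, 4), axis = 2, extreme = -35)
)

#' Maximum tensioned-kit elongation for one motion pattern
#'
#' Sweeps the wrist pose and returns the largest elongation attained by the
#' pattern's tensioned kit pair. Two sweep conventions are available:
#' `"axis"` (default) moves only the pattern's own joint axis from neutral
#' to its ROM extreme, the other axis held at zero — the convention a pure
#' single-pattern exercise realises; `"grid"` takes the maximum over the
#' full 2-D ROM grid, which upper-bounds the elongation but couples
#' flexion/extension excursion into the deviation patterns.
#'
#' @param pattern One of `"flexion"`, `"extension"`, `"radial"`, `"ulnar"`.
#' @param kits List of four [kit_geometry()] objects (default: device
#'   geometry).
#' @param rom Named list with `theta1 = c(min, max)` and
#'   `theta2 = c(min, max)` in degrees.
#' @param sweep `"axis"` or `"grid"`.
#' @param by_deg Sweep resolution in degrees.
#' @return Maximum elongation (mm).
#' @export
pattern_max_elongation <- function(pattern, kits = NULL,
                                   rom = list(theta1 = c(-75, 70),
                                              theta2 = c(-35, 20)),
                                   sweep = c("axis", "grid"), by_deg = 1) {
  sweep <- match.arg(sweep)
  pat <- .rtd_patterns[[match.arg(pattern, names(.rtd_patterns))]]
  if (is.null(kits)) kits <- lapply(1:4, kit_geometry)
  kk <- kits[pat$kits]
  if (sweep == "axis") {
    ex <- pat$extreme
    grid <- seq(0, ex, by = sign(ex) * by_deg)
    vals <- lapply(kk, function(k) {
      if (pat$axis == 1) kit_elongation(k, deg2rad(grid), 0)
      else kit_elongation(k, 0, deg2rad(grid))
    })
  } else {
    t1 <- deg2rad(seq(rom$theta1[1], rom$theta1[2], by = by_deg))
    t2 <- deg2rad(seq(rom$theta2[1], rom$theta2[2], by = by_deg))
    vals <- lapply(kk, function(k)
      outer(t1, t2, function(a, b) kit_elongation(k, a, b)))
  }
  max(vapply(vals, max, numeric(1)))
}

#' Per-pattern resistance-force table of the device
#'
#' For each motion pattern and each supplied spring, computes
#' `F = 2 k x_max` where `x_max` is the pattern's maximum tensioned-kit
#' elongation from [pattern_max_elongation()] and `k` the Eq-of-state spring
#' rate from [spring_constant()].
#'
#' @param specs A list of [spring_spec()] objects, optionally named; by
#'   default the low- (0.8 mm wire) and high- (1.0 mm) resistance springs.
#' @inheritParams pattern_max_elongation
#' @return A data.frame with one row per spring and columns `spring`,
#'   `k_N_per_m`, then one force column (N) per pattern. The attribute
#'   `"elongation_mm"` carries the per-pattern elongations.
#' @export
resistance_table <- function(specs = list(low = spring_spec(d_wire = 0.8),
                                          high = spring_spec(d_wire = 1.0)),
                             kits = NULL,
                             rom = list(theta1 = c(-75, 70),
                                        theta2 = c(-35, 20)),
                             sweep = c("axis", "grid"), by_deg = 1) {
  sweep <- match.arg(sweep)
  if (is.null(kits)) kits <- lapply(1:4, kit_geometry)
  pats <- names(.rtd_patterns)
  x_mm <- vapply(pats, pattern_max_elongation, numeric(1),
                 kits = kits, rom = rom, sweep = sweep, by_deg = by_deg)
  ks <- vapply(specs, spring_constant, numeric(1))
  nm <- names(specs)
  if (is.null(nm)) nm <- paste0("spring", seq_along(specs))
  out <- data.frame(spring = nm, k_N_per_m = ks)
  for (p in pats) out[[p]] <- group_force(ks, x_mm[[p]] * 1e-3)
  rownames(out) <- NULL
  attr(out, "elongation_mm") <- x_mm
  out
}
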