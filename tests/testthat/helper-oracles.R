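# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit rotation matrices, central differences,
# and coordinate geometry built from first principles.

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Rodrigues rotation of point p about unit axis n by ang (rad).
rotate_about_axis <- function(p, n, ang) {
  n <- n / sqrt(sum(n^2))
  p * cos(ang) + cross3(n, p) * sin(ang) + n * sum(n * p) * (1 - cos(ang))
}

# Central difference of f at x.
central_diff <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Planar distance between the hand and forearm spring anchors, built from
# the anchor coordinates directly rather than the expanded radicand.
planar_anchor_distance <- function(l1, l3, l4, theta) {
  p_hand <- c(l1 - l3 * sin(theta), l3 * cos(theta))
  p_forearm <- c(0, l4)
  sqrt(sum((p_hand - p_forearm)^2))
}

expect_equal_tol <- function(object, expected, tol) {
  expect_equal(object, expected, tolerance = tol)
}
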