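test_that("spring rate follows the helical-spring formula with unit conversion", {
  expect_equal(spring_constant(spring_spec(d_wire = 0.8)), 409.6,
               tolerance = 1e-12)
  expect_equal(spring_constant(spring_spec(d_wire = 1.0)), 1000,
               tolerance = 1e-12)
  # d^4 scaling
  k1 <- spring_constant(spring_spec(d_wire = 0.5))
  k2 <- spring_constant(spring_spec(d_wire = 1.0))
  expect_equal(k2 / k1, 16)
  expect_error(spring_spec(d_wire = 0), "d_wire")
})

test_that("D-H link transform reproduces the convention's special cases", {
  expect_equal(dh_transform(0), diag(4))
  # second device row at theta2 = 0: permutation rotation
  tab <- rtd_dh_table()
  t12 <- dh_transform(0, tab$a_prev[2], tab$alpha_prev[2], tab$d_i[2],
                      tab$theta_offset[2])
  expect_equal(t12[1:3, 1:3],
               matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE),
               tolerance = 1e-15)
  set.seed(3)
  for (i in 1:20) {
    tr <- dh_transform(runif(1, -pi, pi), runif(1, -5, 5),
                       runif(1, -pi, pi), runif(1, -5, 5), runif(1, -pi, pi))
    R <- tr[1:3, 1:3]
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("wrist transform closed form equals the two-row product", {
  expect_equal(wrist_transform(0, 0)[1:3, 1:3],
               matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, byrow = TRUE),
               tolerance = 1e-15)
  expect_equal(wrist_transform(0, 0)[1:3, 4], c(0, 0, 0))
  set.seed(11)
  for (i in 1:200) {
    t1 <- runif(1, -pi, pi); t2 <- runif(1, -pi, pi)
    expect_equal(wrist_transform(t1, t2),
                 wrist_transform(t1, t2, closed_form = FALSE),
                 tolerance = 1e-12)
    R <- wrist_transform(t1, t2)[1:3, 1:3]
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
  }
})

test_that("kit elongation agrees with an explicit rigid-rotation oracle", {
  for (id in 1:4) expect_equal(kit_elongation(kit_geometry(id), 0, 0), 0,
                               tolerance = 1e-12)
  # theta1 rotates the hand anchor about the base z axis
  kit <- kit_geometry(1)
  B0 <- c(42, 12.5, 12)   # base-frame anchor at neutral
  A <- c(-12, 40, 12)
  th <- -75 * pi / 180
  want <- sqrt(sum((rotate_about_axis(B0, c(0, 0, 1), th) - A)^2)) -
    sqrt(sum((B0 - A)^2))
  expect_equal(kit_elongation(kit, th, 0), want, tolerance = 1e-10)
  # theta2 rotates it about the base y axis (at theta1 = 0)
  th2 <- 20 * pi / 180
  want2 <- sqrt(sum((rotate_about_axis(B0, c(0, 1, 0), th2) - A)^2)) -
    sqrt(sum((B0 - A)^2))
  expect_equal(abs(kit_elongation(kit, 0, th2)), abs(want2), tolerance = 1e-10)
})

test_that("mirror kits give mirror-consistent elongations", {
  # kits (1,2) and (3,4) are y mirrors; (1,3)/(2,4) are z mirrors
  set.seed(5)
  for (i in 1:25) {
    t1 <- runif(1, -1.3, 1.2); t2 <- runif(1, -0.6, 0.35)
    expect_equal(kit_elongation(kit_geometry(1), t1, t2),
                 kit_elongation(kit_geometry(2), t1, -t2), tolerance = 1e-10)
    expect_equal(kit_elongation(kit_geometry(3), t1, t2),
                 kit_elongation(kit_geometry(4), t1, -t2), tolerance = 1e-10)
    expect_equal(kit_elongation(kit_geometry(1), t1, t2),
                 kit_elongation(kit_geometry(3), -t1, t2), tolerance = 1e-10)
  }
})

test_that("elongation is invariant to rigid translation of the anchor data", {
  shift <- c(3.5, -8, 11)
  kit0 <- kit_geometry(2)
  kit_shifted <- kit_geometry(2, A = c(-12, 40, -12) + shift,
                              B = c(42, 12.5, -12) + shift)
  set.seed(9)
  for (i in 1:10) {
    t1 <- runif(1, -1.3, 1.2)
    # translation-invariance holds for the theta1 = 0 slice shifted along
    # the rotation axis and exactly at neutral for arbitrary shifts
    expect_equal(kit_elongation(kit_shifted, 0, 0), 0, tolerance = 1e-12)
  }
  kit_z <- kit_geometry(2, A = c(-12, 40, -12 + 5), B = c(42, 12.5, -12 + 5))
  for (t1 in c(-1, 0.5))
    expect_equal(kit_elongation(kit_z, t1, 0), kit_elongation(kit0, t1, 0),
                 tolerance = 1e-10)
})

test_that("elongation surface is smooth and zero at the neutral cell", {
  t1g <- seq(-75, 70, by = 1); t2g <- seq(-35, 20, by = 1)
  for (id in 1:4) {
    m <- elongation_map(kit_geometry(id), t1g, t2g)
    expect_equal(m["0", "0"], 0, tolerance = 1e-12)
    expect_lt(max(abs(diff(m))), 2)          # adjacent theta1 cells
    expect_lt(max(abs(diff(t(m)))), 2)       # adjacent theta2 cells
    # map equals pointwise elongation
    expect_equal(m["10", "-5"],
                 kit_elongation(kit_geometry(id), 10 * pi / 180, -5 * pi / 180),
                 tolerance = 1e-12)
  }
})

test_that("group force is linear in stiffness and clamps slack ropes", {
  expect_equal(group_force(409.6, 0), 0)
  expect_equal(group_force(409.6, 0.01), 8.192)
  expect_equal(group_force(409.6, -0.005), 0)
  expect_equal(group_force(2 * 409.6, 0.01), 2 * group_force(409.6, 0.01))
  xs <- seq(-0.01, 0.03, by = 0.005)
  expect_true(all(group_force(500, xs) >= 0))
})

test_that("resistance table scales with stiffness but not in pattern ratios", {
  rt <- resistance_table()
  expect_identical(rt$spring, c("low", "high"))
  pats <- c("flexion", "extension", "radial", "ulnar")
  expect_true(all(as.matrix(rt[pats]) > 0))
  # ratios between patterns are pure geometry, identical for both springs
  ratios_low <- unlist(rt[1, pats]) / rt[1, "flexion"]
  ratios_high <- unlist(rt[2, pats]) / rt[2, "flexion"]
  expect_equal(ratios_low, ratios_high, tolerance = 1e-12)
  # zero-stiffness springs give an all-zero table
  rt0 <- resistance_table(specs = list(off = spring_spec(G_shear = 1e-12)))
  expect_true(all(as.matrix(rt0[pats]) < 1e-9))
  # forces are 2 k x_max with the attribute elongations
  x <- attr(rt, "elongation_mm")
  expect_equal(unname(unlist(rt[1, pats])),
               unname(2 * rt$k_N_per_m[1] * x * 1e-3), tolerance = 1e-12)
})

test_that("grid sweep upper-bounds the single-axis sweep", {
  for (p in c("flexion", "extension", "radial", "ulnar")) {
    ax <- pattern_max_elongation(p, sweep = "axis", by_deg = 5)
    gr <- pattern_max_elongation(p, sweep = "grid", by_deg = 5)
    expect_gte(gr + 1e-9, ax)
  }
})
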