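make_series <- function(angle, fs = 50, ...) {
  t <- (seq_along(angle) - 1) / fs
  joint_angle_series(t, angle, ...)
}

triangle_wave <- function(n_cycles, lo, hi, samples_per_cycle = 100) {
  half <- samples_per_cycle / 2
  one <- c(seq(lo, hi, length.out = half), seq(hi, lo, length.out = half))
  rep(one, n_cycles)
}

test_that("series constructor validates sampling", {
  expect_error(joint_angle_series(c(0, 0.1, 0.05), c(1, 2, 3)),
               "strictly increasing")
  expect_error(joint_angle_series(c(0, 0.1, 0.3), c(1, 2, 3)), "jitter")
  s <- make_series(rep(0, 100), fs = 50)
  expect_equal(s$fs, 50)
})

test_that("hysteresis counting requires crossing upper then lower", {
  thr <- threshold_pair(45, 30)
  expect_equal(count_reps(make_series(rep(0, 200)), thr), 0L)
  # 7 triangle cycles spanning [-40, 60] each cross both thresholds once
  s <- make_series(triangle_wave(7, -40, 60))
  expect_equal(count_reps(s, thr), 7L)
  # oscillation between the thresholds never counts
  s_mid <- make_series(35 + 5 * sin(seq(0, 40, by = 0.02)))
  expect_equal(count_reps(s_mid, thr), 0L)
  # count never exceeds the number of upward crossings of `upper`
  a <- triangle_wave(5, 20, 50)
  n_up <- sum(diff(a > 45) == 1)
  expect_lte(count_reps(make_series(a), thr), n_up)
})

test_that("negative-lower patterns count one rep per full reciprocation", {
  thr <- threshold_pair(30, -30)
  a <- 40 * sin(seq(0, 6 * 2 * pi, length.out = 1200))  # 6 full cycles
  expect_equal(count_reps(make_series(a), thr), 6L)
  # half-swings that never reach -30 don't count
  a_half <- pmax(40 * sin(seq(0, 6 * 2 * pi, length.out = 1200)), -20)
  expect_equal(count_reps(make_series(a_half), thr), 0L)
})

test_that("counting is invariant to resampling and time warps", {
  cfg <- angle_trace_config("elbow_fe",
                            per_rep_amplitudes = c(60, 60, 40, 60, 40),
                            noise_sd = 0, joint = "elbow")
  ser <- gen_angle_trace(cfg)
  thr <- threshold_pair(45, 30)
  n0 <- count_reps(ser, thr)
  expect_equal(n0, 3L)
  # double the sampling rate by linear interpolation
  t2 <- seq(min(ser$t), max(ser$t), by = 1 / (2 * cfg$fs))
  ser2 <- joint_angle_series(t2, approx(ser$t, ser$angle, t2)$y,
                             joint = "elbow")
  expect_equal(count_reps(ser2, thr), n0)
  # amplitude-preserving time warp: stretch the clock uniformly
  ser3 <- joint_angle_series(ser$t * 3, ser$angle, joint = "elbow")
  expect_equal(count_reps(ser3, thr), n0)
})

test_that("minimum-duration flag suppresses too-fast repetitions", {
  a <- triangle_wave(3, -40, 60)  # 1 s per cycle at fs 100
  s <- make_series(a, fs = 100)
  thr <- threshold_pair(45, 30)
  expect_equal(count_reps(s, thr), 3L)
  expect_equal(count_reps(s, thr, min_duration = 10), 0L)
})

test_that("ROM extraction recovers configured per-rep amplitudes", {
  amps <- c(60, 55, 50, 45, 40)
  cfg <- angle_trace_config(per_rep_amplitudes = amps, noise_sd = 0.5,
                            seed = 42L)
  ser <- gen_angle_trace(cfg)
  rom <- extract_rom(ser)
  expect_equal(nrow(rom$reps), 5)
  expect_equal(rom$reps$peak_deg, amps, tolerance = 3 * 0.5 / min(amps))
  expect_lt(abs(rom$max - 60), 3 * 0.5 + 1)
  # constant trace: degenerate ROM, no reps
  romc <- extract_rom(make_series(rep(4, 100)))
  expect_equal(c(romc$min, romc$max), c(4, 4))
  expect_equal(nrow(romc$reps), 0)
  # pure sine amplitude 50: global range within one sample of +/-50
  s <- make_series(50 * sin(seq(0, 10 * pi, length.out = 2000)))
  expect_lt(abs(s$angle[which.max(s$angle)] - 50), 0.1)
  rs <- extract_rom(s)
  expect_equal(c(rs$min, rs$max), c(-50, 50), tolerance = 1e-2)
})

test_that("functional-ROM compliance is checked per direction", {
  pass <- check_functional_rom(list(min = -75, max = 70), "fe")
  expect_true(all(pass))
  border <- check_functional_rom(list(min = -39.9, max = 40), "fe")
  expect_identical(unname(border), c(FALSE, TRUE))
  zero <- check_functional_rom(list(min = 0, max = 0), "ru")
  expect_false(any(zero))
  expect_error(check_functional_rom(list(min = 0, max = 0), "sideways"))
})

test_that("relative joint angle matches a rotation-matrix oracle", {
  expect_equal(as.numeric(relative_joint_angle(c(10, 20, 30), c(10, 20, 30))),
               0, tolerance = 1e-12)
  # forearm level, hand pitched +30 degrees
  expect_equal(as.numeric(relative_joint_angle(c(0, 30, 0), c(0, 0, 0), "y")),
               30, tolerance = 1e-12)
  # random pairs: recomposing the extracted Z-Y-X angles reproduces the
  # relative rotation matrix
  set.seed(13)
  for (i in 1:25) {
    h <- runif(3, -80, 80); f <- runif(3, -80, 80)
    yaw <- as.numeric(relative_joint_angle(h, f, "z"))
    pitch <- as.numeric(relative_joint_angle(h, f, "y"))
    roll <- as.numeric(relative_joint_angle(h, f, "x"))
    Rrel <- t(wristexo:::euler_zyx_to_matrix(f)) %*%
      wristexo:::euler_zyx_to_matrix(h)
    expect_equal(wristexo:::euler_zyx_to_matrix(c(yaw, pitch, roll)), Rrel,
                 tolerance = 1e-9)
  }
  # gimbal-degenerate pitch is flagged
  g <- relative_joint_angle(c(0, 90, 0), c(0, 0, 0), "z")
  expect_true(attr(g, "gimbal"))
})
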