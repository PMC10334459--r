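make_angle_stream <- function(elbow_dy, fps = 10, n = 21) {
  # both elbows at the given vertical offset from their shoulders
  frames <- lapply(seq_len(n), function(k) {
    make_body_frame(
      t = (k - 1) / fps,
      shoulders = list(left = c(460, 100), right = c(200, 100)),
      elbows = list(left = c(520, 100 + elbow_dy), right = c(140, 100 + elbow_dy))
    )
  })
  make_body_stream(frames)
}

test_that("arm angle follows the plane-geometry convention (y down, 0 = horizontal)", {
  s0 <- arm_angle_series(make_angle_stream(0), smooth_window_s = 0.5)
  expect_equal(s0$theta_left[1], 0)
  expect_equal(s0$theta_right[1], 0)

  s_down <- arm_angle_series(make_angle_stream(60), smooth_window_s = 0.5)
  expect_equal(s_down$theta_left[1], -45)
  s_up <- arm_angle_series(make_angle_stream(-60), smooth_window_s = 0.5)
  expect_equal(s_up$theta_right[1], 45)

  short <- make_body_frame(
    shoulders = list(left = c(460, 100), right = c(200, 100)),
    elbows = list(left = c(463, 100), right = c(140, 100))
  )
  expect_error(arm_angle_series(make_body_stream(replicate(11, short, simplify = FALSE) |>
    (\(fr) { for (k in seq_along(fr)) fr[[k]]$t <- (k - 1) / 10; fr })())),
    class = "mgce_geometry_error")
})

test_that("mirror flips leave theta unchanged horizontally and negate it vertically", {
  g <- gen_body_stream(motion_scenario("arm_hold", duration = 10, fps = 10,
                                       onset = 4, slope = -8, seed = 3))
  flip <- function(stream, axis) {
    frames <- lapply(stream$frames, function(f) {
      p <- f$points
      if (axis == "x") p[, 1] <- f$frame_size[1] - p[, 1]
      if (axis == "y") p[, 2] <- f$frame_size[2] - p[, 2]
      landmark_frame(f$t, p, "body33", conf = f$conf, frame_size = f$frame_size)
    })
    landmark_stream(frames)
  }
  base <- arm_angle_series(g$stream)
  hor <- arm_angle_series(flip(g$stream, "x"))
  ver <- arm_angle_series(flip(g$stream, "y"))
  expect_equal(hor$theta_left, base$theta_left, tolerance = 1e-9)
  expect_equal(ver$theta_left, -base$theta_left, tolerance = 1e-9)
})

test_that("drift onset honours threshold and hold rules", {
  fps <- 10
  t <- seq(0, 120, by = 1 / fps)
  step_stream <- function(angles) {
    frames <- lapply(seq_along(t), function(k) {
      dy <- 80 * tan(-angles[k] * pi / 180)
      make_body_frame(t = t[k],
                      shoulders = list(left = c(460, 100), right = c(200, 100)),
                      elbows = list(left = c(540, 100 + dy), right = c(120, 100 + dy)))
    })
    arm_angle_series(make_body_stream(frames))
  }
  # constant horizontal: no drift
  expect_true(is.na(detect_arm_drift(step_stream(rep(0, length(t))))$left))

  # clean step to -10 deg at t = 95
  ang <- ifelse(t >= 95, -10, 0)
  onset <- detect_arm_drift(step_stream(ang), threshold_deg = 5, hold_s = 1)$left
  expect_lt(abs(onset - 95), 0.5)

  # a 0.5 s dip does not satisfy a 1 s hold
  dip <- ifelse(t >= 95 & t < 95.5, -10, 0)
  expect_true(is.na(detect_arm_drift(step_stream(dip), threshold_deg = 5,
                                     hold_s = 1)$left))
})

test_that("drift onset is recovered within 1 s on seeded noisy fixtures", {
  n_fix <- 50
  hits <- 0L
  withr::with_seed(123, onsets <- runif(n_fix, 5, 115))
  for (i in seq_len(n_fix)) {
    g <- gen_body_stream(motion_scenario("arm_hold", duration = 120, fps = 15,
                                         jitter_sigma = 1, onset = onsets[i],
                                         slope = -10, seed = i))
    dr <- detect_arm_drift(arm_angle_series(g$stream))
    d <- suppressWarnings(min(dr$left, dr$right, na.rm = TRUE))
    if (is.finite(d) && abs(d - onsets[i]) <= 1) hits <- hits + 1L
  }
  expect_gte(hits / n_fix, 0.95)
})

test_that("linear arm decay slope is recovered within 5%", {
  g <- gen_body_stream(motion_scenario("arm_hold", duration = 120, fps = 15,
                                       jitter_sigma = 1, onset = 0,
                                       slope = -0.3, seed = 21))
  s <- arm_angle_series(g$stream)
  fit <- mgcekit:::ols_slope(s$t, s$theta_left)
  expect_lt(abs(fit$slope - (-0.3)) / 0.3, 0.05)
})

test_that("the smoother preserves low-order polynomials and damps noise", {
  fs <- 30
  t <- seq(0, 10, by = 1 / fs)
  poly <- 2 + 0.5 * t - 0.1 * t^2 + 0.01 * t^3
  expect_equal(smooth_series(poly, fs, order = 4, window_s = 1), poly,
               tolerance = 1e-9)
  withr::with_seed(5, noise <- rnorm(length(t)))
  expect_lt(var(smooth_series(noise, fs, order = 4, window_s = 1)), var(noise))
  expect_error(smooth_series(noise, fs, window_s = 20),
               class = "mgce_parameter_error")
})

test_that("stand kinematics recover rise speed, calibration and sway", {
  fps <- 60
  t <- seq(0, 3, by = 1 / fps)
  y <- ifelse(t < 1, 400, ifelse(t < 2, 400 - 200 * (t - 1), 200))
  x <- 400 + 3 * sin(2 * pi * 10 * t)   # 10 Hz wobble, amplitude 3 px
  frames <- lapply(seq_along(t), function(k) {
    make_body_frame(t = t[k], hips = list(left = c(440 + (x[k] - 400), y[k]),
                                          right = c(360 + (x[k] - 400), y[k])))
  })
  kin <- stand_kinematics(make_body_stream(frames))
  expect_lt(abs(kin$peak_speed_px_s - 200) / 200, 0.05)
  expect_gte(kin$rise_start, 0.9)
  expect_lte(kin$rise_end, 2.1)
  expect_lt(abs(kin$lateral_sway_px - 3 / sqrt(2)) / (3 / sqrt(2)), 0.05)

  calib <- calibrate_pixels(45, 150)
  kin_cm <- stand_kinematics(make_body_stream(frames), calib = calib)
  expect_equal(kin_cm$peak_speed_cm_s, kin_cm$peak_speed_px_s * 0.3)

  # a perfectly still subject has no rise
  still <- lapply(t, function(tt) {
    make_body_frame(t = tt, hips = list(left = c(440, 400), right = c(360, 400)))
  })
  expect_error(stand_kinematics(make_body_stream(still)),
               class = "mgce_detection_error")
})

test_that("pixel calibration follows its closed form and rejects bad input", {
  expect_equal(calibrate_pixels(45, 150)$scale, 0.3)
  expect_equal(calibrate_pixels(1, 1)$scale, 1)
  expect_error(calibrate_pixels(45, 0), class = "mgce_parameter_error")
  expect_error(calibrate_pixels(-1, 10), class = "mgce_parameter_error")
})
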