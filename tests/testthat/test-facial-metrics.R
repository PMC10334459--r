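test_that("a static rest face gives a flat normalized distance of 1", {
  g <- gen_face_stream(motion_scenario("cheek_puff", duration = 6, fps = 10,
                                       amplitude_px = 0, seed = 1))
  f <- mouth_feature_series(g$stream)
  expect_equal(f$upper_lip_nose_distance, rep(1, nrow(f)), tolerance = 1e-12)
  expect_equal(diff(range(f$mouth_angle)), 0)
  expect_true(all(f$corner_distance > 0))
})

test_that("mouth angle follows plane geometry on explicit corner placement", {
  f <- make_face_frame(modify = function(p) {
    p[49, ] <- c(60, 100); p[55, ] <- c(100, 110)
    p
  })
  s <- landmark_stream(list(f, make_face_frame(t = 0.1, modify = function(p) {
    p[49, ] <- c(60, 100); p[55, ] <- c(100, 110)
    p
  })))
  feats <- mouth_feature_series(s, baseline_window_s = 1)
  expect_equal(feats$mouth_angle[1], atan2(10, 40) * 180 / pi, tolerance = 1e-9)
})

test_that("a cheek puff produces a step in the normalized lip-nose distance", {
  sc <- motion_scenario("cheek_puff", duration = 20, fps = 15,
                        jitter_sigma = 0.3, seed = 12,
                        event_start = 5, event_end = 12, amplitude_px = 6)
  g <- gen_face_stream(sc)
  feats <- mouth_feature_series(g$stream)
  ev <- detect_deformation_events(feats$t, feats$upper_lip_nose_distance,
                                  mask = feats$mask)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$start - 5), 0.35)
  expect_lt(abs(ev$end - 12), 0.35)
  expect_lt(abs(ev$amplitude - g$truth$amplitude_rel) / g$truth$amplitude_rel,
            0.15)
})

test_that("normalized distance is zoom-invariant within 1%", {
  g <- gen_face_stream(motion_scenario("cheek_puff", duration = 8, fps = 10,
                                       jitter_sigma = 0, seed = 2,
                                       event_start = 3, event_end = 6))
  zoomed <- landmark_stream(lapply(g$stream$frames, function(f) {
    landmark_frame(f$t, f$points * 2.5, "face68", conf = f$conf,
                   frame_size = f$frame_size * 2.5)
  }))
  f1 <- mouth_feature_series(g$stream)
  f2 <- mouth_feature_series(zoomed)
  expect_lt(max(abs(f2$upper_lip_nose_distance - f1$upper_lip_nose_distance) /
                  f1$upper_lip_nose_distance), 0.01)
})

test_that("cheek illumination tracks blue-channel steps inside the ROI", {
  n <- 6
  frames_lm <- lapply(seq_len(n) - 1, function(tt) make_face_frame(t = tt))
  stream <- landmark_stream(frames_lm)
  base <- array(100, dim = c(450, 800, 3))
  imgs <- lapply(seq_len(n) - 1, function(tt) {
    img <- base
    if (tt >= 3) img[, 401:800, 3] <- img[, 401:800, 3] + 20  # subject-left side
    img
  })
  s <- cheek_illumination_series(imgs, stream)
  expect_equal(s$mean_blue_left[1], 100)
  expect_equal(s$mean_blue_right, rep(100, n))
  expect_equal(s$mean_blue_left[n] - s$mean_blue_left[1], 20)
  expect_equal(which(diff(s$mean_blue_left) > 10), 3)  # step at t = 3

  # grayscale frames: blue mean equals the gray level
  gray <- lapply(seq_len(n) - 1, function(tt) array(37, dim = c(450, 800, 3)))
  expect_equal(cheek_illumination_series(gray, stream)$mean_blue_right,
               rep(37, n))
})

test_that("deformation event detection follows threshold, merge and noise rules", {
  t <- seq(0, 20, by = 0.1)
  x <- 1 + 0.2 * (t >= 5 & t <= 12)
  ev <- detect_deformation_events(t, x)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 5)
  expect_equal(ev$end, 12)
  expect_equal(ev$amplitude, 0.2)

  withr::with_seed(31, noise <- 1 + rnorm(length(t), 0, 0.01))
  expect_equal(nrow(detect_deformation_events(t, noise, z_threshold = 4)), 0)

  two <- 1 + 0.2 * ((t >= 5 & t <= 8) | (t >= 8.2 & t <= 12))
  expect_equal(nrow(detect_deformation_events(t, two)), 1)

  expect_error(detect_deformation_events(t[1:5], x[1:5]),
               class = "mgce_input_error")
})

test_that("injected step events are recovered within 2 frames (seeded fixtures)", {
  fps <- 15
  t <- seq(0, 20, by = 1 / fps)
  hits <- 0L
  for (i in 1:100) {
    withr::with_seed(i, {
      start <- runif(1, 3, 10)
      dur <- runif(1, 1.5, 5)
      x <- 1 + rnorm(length(t), 0, 0.01) + 0.08 * (t >= start & t <= start + dur)
    })
    ev <- detect_deformation_events(t, x)
    if (nrow(ev) == 1 &&
        abs(ev$start - start) <= 2 / fps + 1 / fps &&
        abs(ev$end - (start + dur)) <= 2 / fps + 1 / fps) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / 100, 0.95)
})

test_that("the side switch is located between the two sustained pushes", {
  fps <- 10
  t <- seq(0, 9.9, by = 1 / fps)
  angle <- ifelse(t < 5, 5, -5)
  sw <- side_switch_detector(t, angle)
  expect_lt(abs(sw - 5), 0.15)

  expect_true(is.na(side_switch_detector(t, rep(3, length(t)))))
  withr::with_seed(17, noise <- rnorm(length(t), 0, 0.3))
  expect_true(is.na(side_switch_detector(t, noise)))
})

test_that("push direction antisymmetry: opposite pushes negate the angle series", {
  left <- gen_face_stream(motion_scenario("tongue_to_cheek", duration = 10,
                                          fps = 10, amplitude_px = 5, seed = 5))
  right <- gen_face_stream(motion_scenario("tongue_to_cheek", duration = 10,
                                           fps = 10, amplitude_px = -5, seed = 5))
  fl <- mouth_feature_series(left$stream)
  fr <- mouth_feature_series(right$stream)
  expect_equal(fl$mouth_angle, -fr$mouth_angle, tolerance = 1e-9)
  # and the detected switch matches the scenario ground truth
  expect_lt(abs(side_switch_detector(fl$t, fl$mouth_angle) - left$truth$switch_time),
            0.15)
})
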