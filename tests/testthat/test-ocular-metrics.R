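test_that("ptosis series assembles per-frame measures and masks bad frames", {
  sc <- motion_scenario("ptosis", duration = 60, fps = 2, seed = 1,
                        decay_fraction = 0, noise_frac = 0)
  g <- gen_ptosis_sequence(sc)
  s <- ptosis_series(g$geoms, g$times)
  expect_s3_class(s, "ptosis_series")
  expect_equal(nrow(s), length(g$times))
  expect_equal(diff(range(s$d_lid_pupil)), 0)  # constant stream -> constant series

  # all frames unusable -> insufficient data
  bad <- lapply(g$geoms, function(x) { x$quality <- "closed"; x })
  expect_error(ptosis_series(bad, g$times), class = "mgce_insufficient_data")
  # too short a span
  expect_error(ptosis_series(g$geoms[1:20], g$times[1:20], min_span_s = 30),
               class = "mgce_insufficient_data")
})

test_that("linear decay fit recovers slope and percent decay exactly on clean data", {
  t <- seq(0, 60, by = 0.5)
  s <- measures_series(t, 10 - 0.025 * t)
  fit <- fit_linear_decay(s, "d_lid_pupil")
  expect_equal(fit$slope, -0.025, tolerance = 1e-10)
  expect_equal(fit$percent_decay, 15, tolerance = 1e-8)
  expect_lt(fit$p_value, 0.001)

  flat <- fit_linear_decay(measures_series(t, rep(10, length(t))))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$percent_decay, 0, tolerance = 1e-10)
  expect_gt(flat$p_value, 0.05)
})

test_that("percent decay is recovered within 2 points under measurement noise", {
  t <- seq(0, 60, by = 0.1)
  withr::with_seed(99, {
    y <- 10 - 0.025 * t + rnorm(length(t), 0, 0.2)
  })
  fit <- fit_linear_decay(measures_series(t, y))
  expect_lt(abs(fit$percent_decay - 15), 2)
})

test_that("decay recovery holds across injected fractions (seeded replicates)", {
  fractions <- c(5, 10, 15, 20)
  hits <- 0L; total <- 0L
  for (f in fractions) {
    for (rep in 1:25) {
      g <- gen_ptosis_sequence(motion_scenario(
        "ptosis", duration = 60, fps = 10, seed = 1000 * f + rep,
        decay_fraction = f / 100, noise_frac = 0.02
      ))
      fit <- fit_linear_decay(ptosis_series(g$geoms, g$times))
      total <- total + 1L
      if (abs(fit$percent_decay - f) <= 2) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("percent decay and significance are invariant under pixel rescaling", {
  t <- seq(0, 60, by = 0.2)
  withr::with_seed(7, y <- 8 - 0.02 * t + rnorm(length(t), 0, 0.1))
  f1 <- fit_linear_decay(measures_series(t, y))
  f3 <- fit_linear_decay(measures_series(t, 3.7 * y))
  expect_equal(f3$percent_decay, f1$percent_decay, tolerance = 1e-9)
  expect_equal(f3$p_value, f1$p_value, tolerance = 1e-9)
})

test_that("barycentric alignment coordinates follow their definition", {
  # inner iris border midway between corners -> b = 0.5
  gl <- flat_eye_geometry(pupil = c(20, 10), iris = c(12, 28))
  # left-eye patch: inner (nasal) corner at x = 0, outer at x = 40
  b <- mgcekit:::barycentric_coord(gl, 0, 40)
  expect_equal(b, 0.3)   # inner border 12 over a 40 px span
  gmid <- flat_eye_geometry(iris = c(20, 30))
  expect_equal(mgcekit:::barycentric_coord(gmid, 0, 40), 0.5)

  # 2 px shift over a 40 px span -> delta b = 0.05
  gshift <- flat_eye_geometry(iris = c(14, 28))
  expect_equal(mgcekit:::barycentric_coord(gshift, 0, 40) - b, 0.05)

  expect_error(mgcekit:::barycentric_coord(gl, 0, 3),
               class = "mgce_geometry_error")
})

test_that("mirror-symmetric eyes produce zero misalignment", {
  n <- 61
  t <- seq(0, 30, length.out = n)
  geoms <- replicate(n, flat_eye_geometry(iris = c(14, 26)), simplify = FALSE)
  s <- alignment_series(geoms, geoms, t,
                        corners_left = c(0, 40), corners_right = c(0, 40))
  expect_equal(s$b_left, s$b_right)
  expect_true(all(s$misalignment == 0))
  summ <- alignment_summary(s)
  expect_true(summ$steady)
  expect_equal(summ$drift_slope, 0, tolerance = 1e-12)
})

test_that("alignment coordinate is invariant under horizontal eye translation", {
  g1 <- flat_eye_geometry(iris = c(14, 26))
  g2 <- flat_eye_geometry(iris = c(14, 26) + 5)
  expect_equal(mgcekit:::barycentric_coord(g1, 0, 40),
               mgcekit:::barycentric_coord(g2, 5, 45), tolerance = 1e-12)
})

test_that("alignment summary detects ramps and spikes", {
  t <- seq(0, 60, by = 0.5)
  ramp <- structure(
    data.frame(t = t, b_left = 0.5, b_right = 0.5,
               misalignment = 0.1 * t / 60),
    class = c("alignment_series", "data.frame")
  )
  summ <- alignment_summary(ramp)
  expect_equal(summ$drift_slope, 0.1 / 60, tolerance = 1e-6)

  spiked <- ramp
  spiked$misalignment <- rep(0, length(t))
  spiked$misalignment[60] <- 0.2
  expect_false(alignment_summary(spiked)$steady)
})
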