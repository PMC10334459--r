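# Seeded synthetic-fixture generators with analytic ground truth.
#
# Every metric module in the toolbox is exercised against these generators,
# which emulate the telehealth acquisition regime: ~40x20 px eye patches,
# landmark streams at webcam frame rates with Gaussian jitter, and counting
# audio as tone bursts over noise. Rendering is deliberately simple (discs
# and parabolic lid occluders), matching the resolution regime the metrics
# target rather than photorealism.

#' Parameters of a synthetic eye scene
#'
#' Geometry is expressed in patch coordinates: the pixel at row i, column j
#' has its centre at (j - 0.5, i - 0.5), origin top-left, y down. The upper
#' lid is the parabola `y = apex + curv * (x - px)^2` (apex is the highest,
#' i.e. smallest-y, point of the opening); the lower lid is
#' `y = apex_lower - curv_lower * (x - px)^2`.
#'
#' @param width,height patch size in pixels (telehealth eye regions are
#'   about 40 x 20)
#' @param pupil_center c(x, y) of the true pupil centre, px
#' @param iris_radius iris disc radius, px
#' @param pupil_radius darker central pupil radius, px
#' @param lid_pupil_distance initial vertical distance from the upper-lid
#'   curve at the pupil column down to the pupil centre, px
#' @param lower_lid_offset vertical distance from pupil centre down to the
#'   lower lid at the pupil column, px
#' @param lid_curvature,lower_lid_curvature parabola coefficients, 1/px
#' @param decay_fraction fraction in `[0, 1)` by which lid_pupil_distance
#'   shrinks linearly over a rendered sequence (ptosis emulation)
#' @param intensities named list: skin, sclera, iris, pupil in `[0, 1]`
#' @param noise_sigma additive Gaussian pixel noise sd
#' @param seed RNG seed
#' @return object of class `eye_scene_params`
#' @export
eye_scene_params <- function(width = 40, height = 20,
                             pupil_center = c(20, 10),
                             iris_radius = 5, pupil_radius = 2,
                             lid_pupil_distance = 5,
                             lower_lid_offset = 6,
                             lid_curvature = 0.035,
                             lower_lid_curvature = 0.02,
                             decay_fraction = 0,
                             intensities = list(skin = 0.75, sclera = 0.92,
                                                iris = 0.25, pupil = 0.08),
                             noise_sigma = 0.05,
                             seed = 1L) {
  p <- list(
    width = as.integer(width), height = as.integer(height),
    pupil_center = as.numeric(pupil_center),
    iris_radius = iris_radius, pupil_radius = pupil_radius,
    lid_pupil_distance = lid_pupil_distance,
    lower_lid_offset = lower_lid_offset,
    lid_curvature = lid_curvature,
    lower_lid_curvature = lower_lid_curvature,
    decay_fraction = decay_fraction,
    intensities = intensities,
    noise_sigma = noise_sigma, seed = as.integer(seed)
  )
  if (p$decay_fraction < 0 || p$decay_fraction >= 1) {
    abort_mgce("decay_fraction must be in [0, 1)", "mgce_parameter_error")
  }
  if (p$iris_radius * 2 > p$height) {
    abort_mgce("iris does not fit inside the patch", "mgce_parameter_error")
  }
  if (p$pupil_center[1] - p$iris_radius < 0 ||
      p$pupil_center[1] + p$iris_radius > p$width ||
      p$pupil_center[2] + p$iris_radius > p$height) {
    abort_mgce("iris geometry extends outside the patch", "mgce_parameter_error")
  }
  structure(p, class = "eye_scene_params")
}

# ground-truth geometry for frame i of n under linear lid descent
eye_truth_geometry <- function(p, frame = 1L, n_frames = 1L) {
  frac <- if (n_frames > 1L) (frame - 1) / (n_frames - 1) else 0
  d <- p$lid_pupil_distance * (1 - p$decay_fraction * frac)
  px <- p$pupil_center[1]; py <- p$pupil_center[2]
  # y = (py - d + curv*px^2) - 2*curv*px*x + curv*x^2
  up <- c(py - d + p$lid_curvature * px^2,
          -2 * p$lid_curvature * px, p$lid_curvature)
  lo <- c(py + p$lower_lid_offset - p$lower_lid_curvature * px^2,
          2 * p$lower_lid_curvature * px, -p$lower_lid_curvature)
  eye_geometry(
    pupil_center = c(px, py),
    iris_x_left = px - p$iris_radius,
    iris_x_right = px + p$iris_radius,
    iris_bottom_y = py + p$iris_radius,
    upper_lid = up, lower_lid = lo,
    quality = "ok"
  )
}

#' Render a synthetic eye-patch sequence with ground truth
#'
#' Renders anti-aliased (supersampled) frames of an iris/pupil disc between
#' two parabolic lid occluders over skin, with optional linear descent of
#' the upper lid (`decay_fraction`) and additive Gaussian pixel noise.
#' Fully deterministic for a fixed seed.
#'
#' @param params an [eye_scene_params()]
#' @param n_frames number of frames
#' @return list with `frames` (list of [eye_patch()]) and `truth`
#'   (list of ground-truth [eye_geometry()] per frame)
#' @export
render_eye_sequence <- function(params, n_frames = 1L) {
  stopifnot(inherits(params, "eye_scene_params"))
  p <- params
  ss <- 3L  # supersampling grid per pixel side
  off <- (seq_len(ss) - 0.5) / ss
  xs <- as.vector(outer(rep(seq_len(p$width) - 1, each = 1), off, `+`))
  # subpixel sample coordinates
  xg <- rep(seq_len(p$width) - 1, each = ss) + rep(off, times = p$width)
  yg <- rep(seq_len(p$height) - 1, each = ss) + rep(off, times = p$height)
  with_seed(p$seed, {
    out <- vector("list", n_frames)
    truth <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      g <- eye_truth_geometry(p, k, n_frames)
      yu <- polyval2(g$upper_lid, xg)   # per x-sample upper lid
      yl <- polyval2(g$lower_lid, xg)
      img_ss <- matrix(p$intensities$skin, nrow = length(yg), ncol = length(xg))
      for (jj in seq_along(xg)) {
        open <- yg > yu[jj] & yg < yl[jj]
        if (!any(open)) next
        dx2 <- (xg[jj] - p$pupil_center[1])^2
        dy <- yg[open] - p$pupil_center[2]
        r2 <- dx2 + dy^2
        v <- rep(p$intensities$sclera, sum(open))
        v[r2 <= p$iris_radius^2] <- p$intensities$iris
        v[r2 <= p$pupil_radius^2] <- p$intensities$pupil
        img_ss[open, jj] <- v
      }
      # average the ss x ss subpixels down to pixel resolution
      img <- matrix(0, p$height, p$width)
      for (i in seq_len(p$height)) {
        ri <- (i - 1L) * ss + seq_len(ss)
        for (j in seq_len(p$width)) {
          ci <- (j - 1L) * ss + seq_len(ss)
          img[i, j] <- mean(img_ss[ri, ci])
        }
      }
      if (p$noise_sigma > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, p$noise_sigma),
                            nrow(img), ncol(img))
      }
      out[[k]] <- eye_patch(img, offset = c(0, 0), side = "left")
      truth[[k]] <- g
    }
    list(frames = out, truth = truth)
  })
}

#' Motion scenario for synthetic landmark streams
#'
#' @param type `"arm_hold"`, `"sit_to_stand"` or `"ptosis"`
#' @param duration seconds
#' @param fps frames per second
#' @param jitter_sigma Gaussian landmark jitter sd, px
#' @param seed RNG seed
#' @param ... scenario parameters: `arm_hold` takes `onset` (s) and `slope`
#'   (deg/s, negative for a falling arm); `sit_to_stand` takes `rise_time`
#'   (s), `sway_amplitude` (px), `y_seated`, `y_standing` (px);
#'   `ptosis` takes `decay_fraction` and `noise_frac` (noise sd as a
#'   fraction of the baseline lid-pupil distance)
#' @return object of class `motion_scenario`
#' @export
motion_scenario <- function(type = c("arm_hold", "sit_to_stand", "ptosis",
                                     "cheek_puff", "tongue_to_cheek"),
                            duration = 120, fps = 30,
                            jitter_sigma = 0, seed = 1L, ...) {
  type <- match.arg(type)
  extra <- list(...)
  defaults <- switch(type,
    arm_hold = list(onset = 95, slope = -2),
    sit_to_stand = list(rise_time = 1.5, sway_amplitude = 4,
                        y_seated = 380, y_standing = 230),
    ptosis = list(decay_fraction = 0.15, noise_frac = 0.02,
                  lid_pupil_distance = 5),
    cheek_puff = list(event_start = 5, event_end = 12, amplitude_px = 6),
    tongue_to_cheek = list(switch_time = NULL, amplitude_px = 5)
  )
  pars <- utils::modifyList(defaults, extra)
  if (!is.null(pars$onset) && pars$onset >= duration) {
    abort_mgce("drift onset must fall within the exercise duration",
               "mgce_parameter_error")
  }
  if (fps <= 0) abort_mgce("fps must be positive", "mgce_parameter_error")
  structure(
    c(list(type = type, duration = duration, fps = fps,
           jitter_sigma = jitter_sigma, seed = as.integer(seed)), pars),
    class = "motion_scenario"
  )
}

# static 33-point body template on a 800x450 frame (only the joints used by
# the motor metrics need anatomical placement)
body_template <- function() {
  pts <- matrix(NA_real_, 33, 2)
  pts[, 1] <- seq(380, 420, length.out = 33)  # filler for unused indices
  pts[, 2] <- seq(60, 80, length.out = 33)
  set_pt <- function(idx0, xy) pts[idx0 + 1L, ] <<- xy
  set_pt(0L, c(400, 60))                      # nose
  set_pt(11L, c(460, 150)); set_pt(12L, c(340, 150))  # shoulders L/R
  set_pt(13L, c(540, 150)); set_pt(14L, c(260, 150))  # elbows (arms out)
  set_pt(15L, c(600, 150)); set_pt(16L, c(200, 150))  # wrists
  set_pt(23L, c(440, 300)); set_pt(24L, c(360, 300))  # hips L/R
  set_pt(25L, c(440, 370)); set_pt(26L, c(360, 370))  # knees
  set_pt(27L, c(440, 430)); set_pt(28L, c(360, 430))  # ankles
  pts
}

#' Generate a synthetic body-landmark stream with ground truth
#'
#' `arm_hold`: both arms horizontal until `onset`, then the elbow falls so
#' the arm angle decreases linearly at `slope` deg/s (clamped at -80 deg).
#' `sit_to_stand`: hip landmarks descend in y (stand up) along a smooth
#' cosine ramp of length `rise_time` centred in the recording, with a
#' sinusoidal lateral sway of amplitude `sway_amplitude` during the rise.
#' Gaussian jitter of sd `jitter_sigma` px is added to every coordinate.
#'
#' @param scenario a [motion_scenario()] of type `arm_hold` or
#'   `sit_to_stand`
#' @return list with `stream` (a body33 [landmark_stream()]) and `truth`
#'   (scenario-specific ground-truth values)
#' @export
gen_body_stream <- function(scenario) {
  stopifnot(inherits(scenario, "motion_scenario"))
  s <- scenario
  if (s$type == "ptosis") {
    abort_mgce("use gen_ptosis_sequence() for the ptosis scenario",
               "mgce_parameter_error")
  }
  t <- seq(0, s$duration, by = 1 / s$fps)
  tmpl <- body_template()
  arm_len <- 80
  with_seed(s$seed, {
    frames <- vector("list", length(t))
    if (s$type == "arm_hold") {
      theta <- pmax(-80, pmin(0, s$slope * (t - s$onset)))
      theta[t < s$onset] <- 0
      th_r <- theta * pi / 180
      for (k in seq_along(t)) {
        pts <- tmpl
        # left arm (11 -> 13) reaches image-right, right arm image-left
        pts[14, ] <- pts[12, ] + c(arm_len * cos(th_r[k]), -arm_len * sin(th_r[k]))
        pts[15, ] <- pts[13, ] + c(-arm_len * cos(th_r[k]), -arm_len * sin(th_r[k]))
        if (s$jitter_sigma > 0) {
          pts <- pts + matrix(stats::rnorm(66, 0, s$jitter_sigma), 33, 2)
        }
        frames[[k]] <- landmark_frame(t[k], pts, "body33",
                                      frame_size = c(800, 450))
      }
      truth <- list(onset = s$onset, slope = s$slope, theta = theta, t = t)
    } else {
      t0 <- s$duration / 2 - s$rise_time / 2
      ramp <- pmin(1, pmax(0, (t - t0) / s$rise_time))
      rng <- s$y_seated - s$y_standing
      y_hip <- s$y_seated - rng * (1 - cos(pi * ramp)) / 2
      in_rise <- ramp > 0 & ramp < 1
      sway <- ifelse(in_rise,
                     s$sway_amplitude * sin(2 * pi * 1.2 * (t - t0)), 0)
      for (k in seq_along(t)) {
        pts <- tmpl
        pts[24, 2] <- y_hip[k]; pts[25, 2] <- y_hip[k]
        pts[24, 1] <- pts[24, 1] + sway[k]
        pts[25, 1] <- pts[25, 1] + sway[k]
        if (s$jitter_sigma > 0) {
          pts <- pts + matrix(stats::rnorm(66, 0, s$jitter_sigma), 33, 2)
        }
        frames[[k]] <- landmark_frame(t[k], pts, "body33",
                                      frame_size = c(800, 450))
      }
      truth <- list(
        rise_start = t0, rise_end = t0 + s$rise_time,
        peak_speed = rng * pi / (2 * s$rise_time),
        sway_rms = s$sway_amplitude / sqrt(2),
        y_hip = y_hip, t = t
      )
    }
    list(stream = landmark_stream(frames), truth = truth)
  })
}

#' Generate a synthetic ptosis geometry sequence
#'
#' Emulates sustained-upgaze lid fatigue: the ground-truth lid-to-pupil
#' distance decays linearly by `decay_fraction` over the recording, and the
#' observed upper-lid position carries Gaussian noise of sd
#' `noise_frac x baseline distance` (measurement jitter of the segmenter).
#'
#' @param scenario a [motion_scenario()] of type `"ptosis"`
#' @return list with `geoms` (list of [eye_geometry()]), `times`, and
#'   `truth` (`d0`, `decay_fraction`, per-frame true distances)
#' @export
gen_ptosis_sequence <- function(scenario) {
  stopifnot(inherits(scenario, "motion_scenario"), scenario$type == "ptosis")
  s <- scenario
  t <- seq(0, s$duration, by = 1 / s$fps)
  n <- length(t)
  d0 <- s$lid_pupil_distance
  d_true <- d0 * (1 - s$decay_fraction * t / s$duration)
  p <- eye_scene_params(lid_pupil_distance = d0, noise_sigma = 0)
  with_seed(s$seed, {
    noise <- stats::rnorm(n, 0, s$noise_frac * d0)
    geoms <- vector("list", n)
    for (k in seq_len(n)) {
      pk <- p
      pk$lid_pupil_distance <- d_true[k] + noise[k]
      geoms[[k]] <- eye_truth_geometry(pk)
    }
    list(geoms = geoms, times = t,
         truth = list(d0 = d0, decay_fraction = s$decay_fraction,
                      d_true = d_true))
  })
}

#' Audio scenario for synthetic counting exercises
#'
#' @param n_bursts number of spoken-number bursts
#' @param burst_s burst duration, s
#' @param pause_s silence between bursts, s
#' @param f0 burst fundamental, Hz
#' @param amplitude burst peak amplitude in `[0, 1]`
#' @param snr_db burst-power to noise-power ratio, dB (`Inf` for no noise)
#' @param fs sampling rate, Hz (>= 8000)
#' @param lead_s silence before the first burst, s
#' @param ramp_s raised-cosine on/off ramp, s
#' @param seed RNG seed
#' @return object of class `audio_scenario`
#' @export
audio_scenario <- function(n_bursts = 50, burst_s = 0.45, pause_s = 0.5,
                           f0 = 220, amplitude = 0.3, snr_db = 20,
                           fs = 8000, lead_s = 1, ramp_s = 0.02, seed = 1L) {
  if (fs < 8000) abort_mgce("fs must be >= 8000 Hz", "mgce_parameter_error")
  if (n_bursts < 0) abort_mgce("n_bursts must be >= 0", "mgce_parameter_error")
  structure(
    list(n_bursts = as.integer(n_bursts), burst_s = burst_s, pause_s = pause_s,
         f0 = f0, amplitude = amplitude, snr_db = snr_db, fs = fs,
         lead_s = lead_s, ramp_s = ramp_s, seed = as.integer(seed)),
    class = "audio_scenario"
  )
}

#' Generate synthetic counting audio with ground-truth segments
#'
#' Sine bursts with raised-cosine onsets/offsets over seeded Gaussian noise
#' at the stated burst-to-noise SNR; ground-truth segment times are the
#' burst on/off boundaries.
#'
#' @param scenario an [audio_scenario()]
#' @return list with `track` (an [audio_track()]) and `truth`
#'   (data.frame of segment `start`/`end` in seconds)
#' @export
gen_counting_audio <- function(scenario) {
  stopifnot(inherits(scenario, "audio_scenario"))
  s <- scenario
  step <- s$burst_s + s$pause_s
  total <- s$lead_s + max(0L, s$n_bursts) * step + s$lead_s
  n <- round(total * s$fs)
  t <- (seq_len(n) - 1) / s$fs
  x <- numeric(n)
  starts <- s$lead_s + (seq_len(s$n_bursts) - 1) * step
  for (st in starts) {
    idx <- which(t >= st & t < st + s$burst_s)
    tt <- t[idx] - st
    env <- rep(1, length(idx))
    if (s$ramp_s > 0) {
      env <- pmin(1, tt / s$ramp_s, (s$burst_s - tt) / s$ramp_s)
      env <- (1 - cos(pi * pmax(0, pmin(1, env)))) / 2
    }
    x[idx] <- x[idx] + s$amplitude * env * sin(2 * pi * s$f0 * tt)
  }
  if (is.finite(s$snr_db) && s$n_bursts > 0 && s$amplitude > 0) {
    noise_sd <- sqrt((s$amplitude^2 / 2) / 10^(s$snr_db / 10))
    x <- x + with_seed(s$seed, stats::rnorm(n, 0, noise_sd))
  }
  truth <- if (s$n_bursts > 0) {
    data.frame(start = starts, end = starts + s$burst_s)
  } else {
    data.frame(start = numeric(0), end = numeric(0))
  }
  list(track = audio_track(x, s$fs), truth = truth)
}

# static 68-point face template on an 800x450 frame; symmetric about x=400
face_template <- function() {
  pts <- matrix(NA_real_, 68, 2)
  # jaw 1..17 along a semi-ellipse (image-left = subject right)
  th <- pi * (0:16) / 16
  pts[1:17, 1] <- 400 - 95 * cos(th)
  pts[1:17, 2] <- 170 + 170 * sin(th)
  # brows 18..27
  pts[18:22, 1] <- seq(320, 375, length.out = 5); pts[18:22, 2] <- 158
  pts[23:27, 1] <- seq(425, 480, length.out = 5); pts[23:27, 2] <- 158
  # nose bridge 28..31 and base 32..36
  pts[28:31, 1] <- 400; pts[28:31, 2] <- seq(178, 226, length.out = 4)
  pts[32:36, 1] <- seq(382, 418, length.out = 5); pts[32:36, 2] <- 240
  pts[34, ] <- c(400, 240)
  # eye hexagons 37..42 (right) and 43..48 (left)
  hexx <- c(-18, -6, 6, 18, 6, -6); hexy <- c(0, -6, -6, 0, 6, 6)
  pts[37:42, 1] <- 340 + hexx; pts[37:42, 2] <- 180 + hexy
  pts[43:48, 1] <- 460 + hexx; pts[43:48, 2] <- 180 + hexy
  # mouth: outer ring 49..60, inner ring 61..68
  pts[49, ] <- c(360, 290); pts[55, ] <- c(440, 290)
  pts[50, ] <- c(370, 283); pts[51, ] <- c(385, 278); pts[52, ] <- c(400, 276)
  pts[53, ] <- c(415, 278); pts[54, ] <- c(430, 283)
  pts[56, ] <- c(430, 297); pts[57, ] <- c(415, 302); pts[58, ] <- c(400, 304)
  pts[59, ] <- c(385, 302); pts[60, ] <- c(370, 297)
  pts[61, ] <- c(365, 290); pts[62, ] <- c(385, 287); pts[63, ] <- c(400, 286)
  pts[64, ] <- c(415, 287); pts[65, ] <- c(435, 290)
  pts[66, ] <- c(415, 293); pts[67, ] <- c(400, 294); pts[68, ] <- c(385, 293)
  pts
}

#' Generate a synthetic face-landmark stream with ground truth
#'
#' `cheek_puff`: the whole mouth shifts down by `amplitude_px` between
#' `event_start` and `event_end` (0.2 s ramps), raising the normalized
#' upper-lip-to-nose distance in a near-step. `tongue_to_cheek`: the mouth
#' corners tilt one way (subject pushes one cheek) and reverse at
#' `switch_time` (default mid-recording).
#'
#' @param scenario a [motion_scenario()] of type `cheek_puff` or
#'   `tongue_to_cheek`
#' @return list with `stream` (a face68 [landmark_stream()]) and `truth`
#' @export
gen_face_stream <- function(scenario) {
  stopifnot(inherits(scenario, "motion_scenario"),
            scenario$type %in% c("cheek_puff", "tongue_to_cheek"))
  s <- scenario
  t <- seq(0, s$duration, by = 1 / s$fps)
  tmpl <- face_template()
  mouth <- 49:68
  with_seed(s$seed, {
    frames <- vector("list", length(t))
    if (s$type == "cheek_puff") {
      ramp <- 0.2
      lvl <- pmin(1, pmax(0, (t - s$event_start) / ramp)) *
        pmin(1, pmax(0, (s$event_end - t) / ramp))
      for (k in seq_along(t)) {
        pts <- tmpl
        pts[mouth, 2] <- pts[mouth, 2] + s$amplitude_px * lvl[k]
        if (s$jitter_sigma > 0) {
          pts <- pts + matrix(stats::rnorm(136, 0, s$jitter_sigma), 68, 2)
        }
        frames[[k]] <- landmark_frame(t[k], pts, "face68",
                                      frame_size = c(800, 450))
      }
      base_dist <- abs(tmpl[52, 2] - tmpl[34, 2])
      truth <- list(event_start = s$event_start, event_end = s$event_end,
                    amplitude_rel = s$amplitude_px / base_dist)
    } else {
      switch_time <- if (is.null(s$switch_time)) s$duration / 2 else s$switch_time
      side <- ifelse(t < switch_time, 1, -1)
      for (k in seq_along(t)) {
        pts <- tmpl
        pts[49, 2] <- pts[49, 2] + s$amplitude_px * side[k]
        pts[55, 2] <- pts[55, 2] - s$amplitude_px * side[k]
        if (s$jitter_sigma > 0) {
          pts <- pts + matrix(stats::rnorm(136, 0, s$jitter_sigma), 68, 2)
        }
        frames[[k]] <- landmark_frame(t[k], pts, "face68",
                                      frame_size = c(800, 450))
      }
      truth <- list(switch_time = switch_time,
                    angle_deg = atan2(2 * s$amplitude_px,
                                      tmpl[55, 1] - tmpl[49, 1]) * 180 / pi)
    }
    list(stream = landmark_stream(frames), truth = truth)
  })
}

#' Write a complete synthetic examination session to disk
#'
#' Emits fixtures for all eight exam items (ptosis measures CSV, alignment
#' CSV, face and body landmark CSVs, counting and single-breath WAVs), the
#' clinical annotations, and a session config referencing them; the result
#' can be fed directly to [run_session()].
#'
#' @param dir output directory (created if needed)
#' @param seed master RNG seed
#' @return path of the written config (YAML), invisibly
#' @export
write_session_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)

  # ptosis: per-frame eye measures with 15% linear decay
  g <- gen_ptosis_sequence(motion_scenario("ptosis", duration = 60, fps = 10,
                                           seed = seed))
  meas <- t(vapply(g$geoms, eye_measures, numeric(3)))
  utils::write.csv(
    data.frame(t = g$times, d_lid_pupil = meas[, "d_lid_pupil"],
               d_lid_lid = meas[, "d_lid_lid"], area = meas[, "area"]),
    file.path(dir, "ptosis_measures.csv"), row.names = FALSE
  )

  # diplopia: quasi-steady barycentric coordinates
  tt <- seq(0, 60, by = 0.1)
  b_noise <- with_seed(seed + 1L, stats::rnorm(2 * length(tt), 0, 0.004))
  utils::write.csv(
    data.frame(t = tt, b_left = 0.52 + b_noise[seq_along(tt)],
               b_right = 0.50 + b_noise[length(tt) + seq_along(tt)]),
    file.path(dir, "alignment.csv"), row.names = FALSE
  )

  # face streams
  cp <- gen_face_stream(motion_scenario("cheek_puff", duration = 20, fps = 15,
                                        jitter_sigma = 0.3, seed = seed + 2L))
  write_landmark_stream(cp$stream, file.path(dir, "cheek_puff_face.csv"))
  tc <- gen_face_stream(motion_scenario("tongue_to_cheek", duration = 12,
                                        fps = 15, jitter_sigma = 0.3,
                                        seed = seed + 3L))
  write_landmark_stream(tc$stream, file.path(dir, "tongue_face.csv"))

  # body streams
  arm <- gen_body_stream(motion_scenario("arm_hold", duration = 125, fps = 15,
                                         jitter_sigma = 1, onset = 95,
                                         slope = -10, seed = seed + 4L))
  write_landmark_stream(arm$stream, file.path(dir, "arm_body.csv"))
  sts <- gen_body_stream(motion_scenario("sit_to_stand", duration = 6,
                                         fps = 30, jitter_sigma = 0.5,
                                         seed = seed + 5L))
  write_landmark_stream(sts$stream, file.path(dir, "stand_body.csv"))

  # audio
  c50 <- gen_counting_audio(audio_scenario(n_bursts = 50, seed = seed + 6L))
  write_wav(c50$track, file.path(dir, "count50.wav"))
  sb <- gen_counting_audio(audio_scenario(n_bursts = 32, burst_s = 0.25,
                                          pause_s = 0.12, seed = seed + 7L))
  write_wav(sb$track, file.path(dir, "single_breath.wav"))

  config <- list(
    seed = seed,
    calibration = list(known_length_cm = 45, measured_px = 150),
    exercises = list(
      ptosis = list(measures_csv = "ptosis_measures.csv", window = c(0, 60)),
      diplopia = list(alignment_csv = "alignment.csv", onset_s = "none"),
      cheek_puff = list(landmarks_csv = "cheek_puff_face.csv",
                        annotation = "normal_seal"),
      tongue_to_cheek = list(landmarks_csv = "tongue_face.csv",
                             annotation = "full_deformity"),
      count50 = list(audio_wav = "count50.wav",
                     dysarthria_onset_count = "none"),
      arm_strength = list(landmarks_csv = "arm_body.csv"),
      single_breath = list(audio_wav = "single_breath.wav", count = 32),
      sit_to_stand = list(landmarks_csv = "stand_body.csv",
                          annotation = "no_difficulty")
    )
  )
  cfg_path <- file.path(dir, "session.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(cfg_path)
}
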