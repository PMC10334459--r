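# Arm-hold and sit-to-stand kinematics from body-pose landmark streams.
#
# Arm angle convention: 0 deg = arm along the image horizontal through the
# shoulders, negative = elbow below the shoulder line (the falling arm of a
# fatiguing hold). With y increasing downward this is
# theta = -atan2(y_elbow - y_shoulder, |x_elbow - x_shoulder|).

#' Polynomial-preserving smoother (Savitzky-Golay)
#'
#' Least-squares polynomial smoothing filter: polynomials up to `order`
#' pass through unchanged (to machine precision), which preserves the
#' low-order trends the drift and rise detectors fit, while attenuating
#' landmark jitter.
#'
#' @param x numeric series (regularly sampled)
#' @param fs sampling rate of `x`, Hz
#' @param order polynomial order (default 4)
#' @param window_s filter window length, seconds (default 1)
#' @return smoothed numeric series, same length as `x`
#' @export
smooth_series <- function(x, fs, order = 4L, window_s = 1) {
  n_win <- round(window_s * fs)
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  n_win <- max(n_win, order + 1L + (order %% 2 == 1L))
  if (n_win %% 2 == 0) n_win <- n_win + 1L
  if (n_win > length(x)) {
    abort_mgce(sprintf("smoothing window (%d samples) exceeds series length (%d)",
                       n_win, length(x)),
               "mgce_parameter_error")
  }
  # NA-tolerant: interpolate over masked gaps before filtering
  if (anyNA(x)) {
    idx <- which(!is.na(x))
    if (length(idx) < 2L) return(x)
    x <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = n_win))
}

#' Arm-angle time series from a body landmark stream
#'
#' Tracks the left arm (shoulder 11 to elbow 13) and right arm (shoulder 12
#' to elbow 14) against the image horizontal through the shoulders.
#'
#' @param stream a `body33` [landmark_stream()]
#' @param smooth_order,smooth_window_s see [smooth_series()]
#' @param min_presence minimum fraction of frames with usable shoulder and
#'   elbow landmarks (default 0.8)
#' @return data.frame of class `arm_angle_series` with columns `t`,
#'   `theta_left`, `theta_right`, smoothed copies, and `mask`
#' @export
arm_angle_series <- function(stream, smooth_order = 4L, smooth_window_s = 1,
                             min_presence = 0.8) {
  stopifnot(inherits(stream, "landmark_stream"), stream$schema == "body33")
  idx <- mgce_landmarks$body33
  angle_of <- function(frame, sh, el) {
    s <- body_point(frame, sh); e <- body_point(frame, el)
    seg <- e - s
    if (sqrt(sum(seg^2)) < 10) {
      abort_mgce("arm segment shorter than 10 px", "mgce_geometry_error")
    }
    -atan2(seg[2], abs(seg[1])) * 180 / pi
  }
  n <- length(stream)
  th_l <- rep(NA_real_, n); th_r <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (stream$flagged[k]) next
    f <- stream$frames[[k]]
    th_l[k] <- angle_of(f, idx$shoulder_left, idx$elbow_left)
    th_r[k] <- angle_of(f, idx$shoulder_right, idx$elbow_right)
  }
  usable <- !is.na(th_l) & !is.na(th_r)
  if (mean(usable) < min_presence) {
    abort_mgce(sprintf("only %.0f%% of frames have usable arm landmarks (need %.0f%%)",
                       100 * mean(usable), 100 * min_presence),
               "mgce_input_error")
  }
  structure(
    data.frame(
      t = stream$t, theta_left = th_l, theta_right = th_r,
      theta_left_smooth = smooth_series(th_l, stream$fps, smooth_order, smooth_window_s),
      theta_right_smooth = smooth_series(th_r, stream$fps, smooth_order, smooth_window_s),
      mask = usable
    ),
    class = c("arm_angle_series", "data.frame"),
    fps = stream$fps
  )
}

#' Detect arm-drift onset
#'
#' The onset is the first time the smoothed arm angle stays below
#' `-threshold_deg` continuously for at least `hold_s` seconds; `NA` if
#' the arm never drifts. The hold requirement rejects transient landmark
#' jitter.
#'
#' @param series an [arm_angle_series()]
#' @param threshold_deg drift threshold, degrees below horizontal (default 5)
#' @param hold_s minimum sustained time below threshold, seconds (default 1)
#' @return list with `left` and `right` onset times (s) or `NA`
#' @export
detect_arm_drift <- function(series, threshold_deg = 5, hold_s = 1) {
  onset_of <- function(theta) {
    below <- theta < -threshold_deg
    below[is.na(below)] <- FALSE
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      dur <- series$t[ends[i]] - series$t[starts[i]]
      if (dur >= hold_s) return(series$t[starts[i]])
    }
    NA_real_
  }
  list(left = onset_of(series$theta_left_smooth),
       right = onset_of(series$theta_right_smooth))
}

#' Pixel-to-physical calibration from a reference object
#'
#' @param known_length_cm physical length of the reference (e.g. the seat
#'   width), cm
#' @param measured_px its length in the image, px
#' @param source reference object id
#' @return list of class `pixel_calibration` with `scale` (cm/px)
#' @export
calibrate_pixels <- function(known_length_cm, measured_px, source = "seat") {
  if (!is_finite_num(known_length_cm) || known_length_cm <= 0 ||
      !is_finite_num(measured_px) || measured_px <= 0) {
    abort_mgce("calibration lengths must be positive", "mgce_parameter_error")
  }
  structure(list(scale = known_length_cm / measured_px, source = source),
            class = "pixel_calibration")
}

#' Sit-to-stand hip kinematics
#'
#' Tracks hip landmarks 23/24. The rise is the interval over which the
#' smoothed mean hip height crosses from within 10% of the seated plateau
#' to within 10% of the standing plateau; speed and acceleration are
#' smoothed finite differences of hip elevation (px/s upward, cm/s when
#' calibrated); lateral sway is the RMS of the hip x-coordinate about its
#' mean during the rise.
#'
#' @param stream a `body33` [landmark_stream()]
#' @param calib optional [calibrate_pixels()] result
#' @param smooth_window_s smoothing window, seconds (default 0.3; shorter
#'   than the arm-hold default so a ~1 s rise is not flattened)
#' @param min_rise_px minimum seated-to-standing hip travel, px (default 20)
#' @param plateau_frac fraction of the recording used for each plateau
#'   estimate (default 0.15)
#' @return list of class `stand_kinematics`
#' @export
stand_kinematics <- function(stream, calib = NULL, smooth_window_s = 0.3,
                             min_rise_px = 20, plateau_frac = 0.15) {
  stopifnot(inherits(stream, "landmark_stream"), stream$schema == "body33")
  idx <- mgce_landmarks$body33
  n <- length(stream)
  hip <- t(vapply(stream$frames, function(f) {
    h <- body_point(f, c(idx$hip_left, idx$hip_right))
    c(x = mean(h[, 1]), y = mean(h[, 2]))
  }, numeric(2)))
  t <- stream$t
  fps <- stream$fps
  ys <- smooth_series(hip[, "y"], fps, 4L, smooth_window_s)
  k <- max(3L, round(plateau_frac * n))
  y_seated <- stats::median(ys[seq_len(k)])
  y_stand <- stats::median(ys[(n - k + 1L):n])
  rng <- y_seated - y_stand
  if (!is.finite(rng) || rng < min_rise_px) {
    abort_mgce("no rise detected: seated and standing plateaus are not separated",
               "mgce_detection_error")
  }
  hi <- y_seated - 0.1 * rng
  lo <- y_stand + 0.1 * rng
  i_end <- which(ys <= lo)[1]
  if (is.na(i_end)) {
    abort_mgce("no rise detected: standing plateau never reached",
               "mgce_detection_error")
  }
  before <- which(ys[seq_len(i_end)] >= hi)
  i_start <- if (length(before)) max(before) else 1L
  dt <- 1 / fps
  # central differences over ~0.2 s: wide enough to suppress the smoother's
  # overshoot at plateau corners, short against a >= 1 s rise
  k <- max(1L, round(0.1 * fps))
  speed <- rep(NA_real_, n)
  ctr <- (k + 1L):(n - k)
  speed[ctr] <- -(ys[ctr + k] - ys[ctr - k]) / (2 * k * dt)  # upward px/s
  accel <- rep(NA_real_, n)
  ctr2 <- (2L * k + 1L):(n - 2L * k)
  accel[ctr2] <- (speed[ctr2 + k] - speed[ctr2 - k]) / (2 * k * dt)
  rise <- seq(i_start, i_end)
  peak_speed <- max(speed[rise], na.rm = TRUE)
  peak_accel <- max(accel[intersect(rise, which(!is.na(accel)))], na.rm = TRUE)
  x_rise <- hip[rise, "x"]
  sway <- sqrt(mean((x_rise - mean(x_rise))^2))
  scale <- if (!is.null(calib)) calib$scale else NA_real_
  structure(
    list(
      t = t, y_hip = hip[, "y"], x_hip = hip[, "x"], y_hip_smooth = ys,
      rise_start = t[i_start], rise_end = t[i_end],
      peak_speed_px_s = peak_speed,
      peak_acceleration_px_s2 = peak_accel,
      lateral_sway_px = sway,
      peak_speed_cm_s = peak_speed * scale,
      lateral_sway_cm = sway * scale,
      calibrated = !is.null(calib)
    ),
    class = "stand_kinematics"
  )
}

#' @export
print.stand_kinematics <- function(x, ...) {
  cat(sprintf(
    "<stand_kinematics> rise [%.2f, %.2f] s, peak speed %.1f px/s%s, sway %.2f px RMS\n",
    x$rise_start, x$rise_end, x$peak_speed_px_s,
    if (x$calibrated) sprintf(" (%.1f cm/s)", x$peak_speed_cm_s) else "",
    x$lateral_sway_px
  ))
  invisible(x)
}
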