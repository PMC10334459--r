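# Cheek-puff and tongue-to-cheek quantification from mouth geometry and
# cheek-region illumination.
#
# The cheek exercises deform the mouth: the normalized upper-lip-to-nose
# distance rises in a near-step during a cheek puff, and the mouth-segment
# angle tilts toward the pushed side during the tongue-to-cheek push. The
# illumination channel (mean blue value in the cheek polygon) is a
# secondary signal, sensitive to lighting.

#' Mouth-geometry feature series from a face landmark stream
#'
#' Per frame: corner distance (landmarks 49-55), signed mouth angle of the
#' 49-to-55 segment versus the image horizontal, vertical inner-lip
#' opening, upper-lip-to-nose-base distance normalized by the inter-ocular
#' distance and by its baseline mean (so the rest value is ~1), lip
#' curvatures (inverse radius of a least-squares circle through the outer
#' lip arc), and a lip-seal flag.
#'
#' @param stream a `face68` [landmark_stream()]
#' @param baseline_window_s window from the start of the stream that
#'   defines the rest baseline, seconds (default 2)
#' @param upper_lip_idx,nose_base_idx landmark indices used for the
#'   normalized distance (1-based; defaults 52 and 34)
#' @param seal_frac seal threshold as a fraction of the baseline inner-lip
#'   gap (default 0.2)
#' @return data.frame of class `mouth_feature_series`
#' @export
mouth_feature_series <- function(stream, baseline_window_s = 2,
                                 upper_lip_idx = 52L, nose_base_idx = 34L,
                                 seal_frac = 0.2) {
  stopifnot(inherits(stream, "landmark_stream"), stream$schema == "face68")
  lm <- mgce_landmarks$face68
  n <- length(stream)
  feats <- lapply(stream$frames, function(f) {
    p49 <- face_point(f, 49L); p55 <- face_point(f, 55L)
    d <- p55 - p49
    eye_r <- colMeans(face_point(f, lm$eye_right))
    eye_l <- colMeans(face_point(f, lm$eye_left))
    interocular <- sqrt(sum((eye_l - eye_r)^2))
    up <- face_point(f, upper_lip_idx)
    nose <- face_point(f, nose_base_idx)
    # inner-lip vertical gap at mouth centre (inner ring 61-68)
    gap <- abs(face_point(f, 67L)[2] - face_point(f, 63L)[2])
    c(corner_distance = sqrt(sum(d^2)),
      mouth_angle = atan2(d[2], d[1]) * 180 / pi,
      vertical_opening = gap,
      upper_lip_nose = abs(up[2] - nose[2]) / interocular,
      lip_curv_up = circle_curvature(face_point(f, 50:54)),
      lip_curv_low = circle_curvature(face_point(f, c(56L, 57L, 58L, 59L, 60L))))
  })
  m <- do.call(rbind, feats)
  mask <- !stream$flagged
  base_idx <- which(mask & stream$t <= stream$t[1] + baseline_window_s)
  if (!length(base_idx)) {
    abort_mgce("baseline window contains no usable frames", "mgce_parameter_error")
  }
  base_dist <- mean(m[base_idx, "upper_lip_nose"])
  base_gap <- mean(m[base_idx, "vertical_opening"])
  structure(
    data.frame(
      t = stream$t,
      corner_distance = m[, "corner_distance"],
      mouth_angle = m[, "mouth_angle"],
      vertical_opening = m[, "vertical_opening"],
      upper_lip_nose_distance = m[, "upper_lip_nose"] / base_dist,
      lip_curvature_up = m[, "lip_curv_up"],
      lip_curvature_low = m[, "lip_curv_low"],
      seal = m[, "vertical_opening"] <= seal_frac * base_gap + 1e-9,
      mask = mask
    ),
    class = c("mouth_feature_series", "data.frame"),
    baseline = list(upper_lip_nose = base_dist, gap = base_gap,
                    window_s = baseline_window_s)
  )
}

# curvature (1/R) of the Kasa least-squares circle through points (n x 2)
circle_curvature <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(0)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(0)
  1 / sqrt(r2)
}

# even-odd point-in-polygon test for pixel centres (vectorized over points)
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Mean blue-channel illumination inside the cheek polygons
#'
#' Skin stretching during a cheek puff alters the local appearance; the
#' mean blue value inside each cheek half tracks that change. The signal
#' is documented as illumination-sensitive: it is not robust to lighting
#' changes and may depend on skin tone, so it supplements, never replaces,
#' the mouth-geometry features.
#'
#' @param frames list of RGB arrays `[height x width x 3]` (values in
#'   `[0, 255]` or `[0, 1]`), one per landmark frame
#' @param stream the matching `face68` [landmark_stream()]
#' @return data.frame of class `cheek_signal` with columns `t`,
#'   `mean_blue_left`, `mean_blue_right`
#' @export
cheek_illumination_series <- function(frames, stream) {
  stopifnot(inherits(stream, "landmark_stream"), stream$schema == "face68")
  n <- length(stream)
  stopifnot(length(frames) == n)
  vals <- t(vapply(seq_len(n), function(k) {
    img <- frames[[k]]
    h <- dim(img)[1]; w <- dim(img)[2]
    f <- stream$frames[[k]]
    out <- c(left = NA_real_, right = NA_real_)
    for (side in c("left", "right")) {
      roi <- cheek_roi(f, side)
      b <- roi$box
      if (b["xmin"] < 0 || b["ymin"] < 0 || b["xmax"] > w || b["ymax"] > h) {
        abort_mgce("cheek ROI extends outside the video frame", "mgce_geometry_error")
      }
      jj <- seq(max(1L, floor(b["xmin"]) + 1L), min(w, ceiling(b["xmax"])))
      ii <- seq(max(1L, floor(b["ymin"]) + 1L), min(h, ceiling(b["ymax"])))
      gx <- rep(jj - 0.5, each = length(ii))
      gy <- rep(ii - 0.5, times = length(jj))
      inside <- points_in_polygon(gx, gy, roi$polygon)
      blue <- img[, , 3][cbind(rep(ii, times = length(jj)),
                               rep(jj, each = length(ii)))]
      out[side] <- mean(blue[inside])
    }
    out
  }, numeric(2)))
  structure(
    data.frame(t = stream$t, mean_blue_left = vals[, "left"],
               mean_blue_right = vals[, "right"]),
    class = c("cheek_signal", "data.frame")
  )
}

#' Detect deformation events in a feature series
#'
#' An event is a span where the feature deviates from its baseline mean by
#' more than `z_threshold` baseline MAD-sigmas for at least
#' `min_duration_s`; events separated by under `merge_gap_s` are merged.
#' The amplitude is the median in-event deviation (signed). A constant
#' baseline with zero in-exercise deviation yields no events. Masked spans
#' (e.g. detector dropouts) are excluded.
#'
#' @param t times, seconds
#' @param x feature values
#' @param z_threshold deviation threshold in baseline MAD units (default 4)
#' @param min_duration_s minimum event duration, seconds (default 0.5)
#' @param baseline_s baseline window from the series start, seconds
#'   (default 2; at least 2 s of pre-exercise baseline is required)
#' @param merge_gap_s merge events closer than this, seconds (default 0.3)
#' @param mask optional logical usability mask; masked samples cannot be
#'   in an event
#' @return data.frame of class `deformation_events` with columns `start`,
#'   `end`, `amplitude`
#' @export
detect_deformation_events <- function(t, x, z_threshold = 4,
                                      min_duration_s = 0.5,
                                      baseline_s = 2, merge_gap_s = 0.3,
                                      mask = NULL) {
  if (t[length(t)] - t[1] < baseline_s) {
    abort_mgce(sprintf("need >= %.1f s of baseline before the exercise", baseline_s),
               "mgce_input_error")
  }
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  base <- x[t <= t[1] + baseline_s & mask]
  m <- mean(base)
  sigma <- stats::mad(base)
  dev <- x - m
  thr <- z_threshold * sigma
  active <- abs(dev) > thr & mask
  active[is.na(active)] <- FALSE
  r <- rle(active)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- data.frame(start = t[starts[r$values]], end = t[ends[r$values]],
                   i0 = starts[r$values], i1 = ends[r$values])
  if (nrow(ev) > 1L) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      if (ev$start[i] - merged$end[nrow(merged)] < merge_gap_s) {
        merged$end[nrow(merged)] <- ev$end[i]
        merged$i1[nrow(merged)] <- ev$i1[i]
      } else {
        merged <- rbind(merged, ev[i, ])
      }
    }
    ev <- merged
  }
  if (nrow(ev)) {
    ev <- ev[ev$end - ev$start >= min_duration_s, , drop = FALSE]
  }
  amp <- vapply(seq_len(nrow(ev)), function(i) {
    stats::median(dev[ev$i0[i]:ev$i1[i]])
  }, numeric(1))
  structure(
    data.frame(start = ev$start, end = ev$end, amplitude = amp),
    class = c("deformation_events", "data.frame"),
    baseline_mean = m, baseline_sigma = sigma
  )
}

#' Detect the left-to-right switch in a tongue-to-cheek exercise
#'
#' The push breaks facial symmetry: the mouth angle holds one sign while
#' one cheek is pushed and the opposite sign after the switch. The switch
#' time is the sign transition between two sustained opposite-sign
#' segments of the centred angle series; `NA` when the series is
#' single-signed (no switch).
#'
#' @param t times, seconds
#' @param angle signed mouth-angle series, degrees
#' @param min_segment_s minimum sustained duration on each side, seconds
#'   (default 1)
#' @param min_amplitude_deg minimum mean absolute centred angle on each
#'   side, degrees (default 1)
#' @return switch time in seconds, or `NA`
#' @export
side_switch_detector <- function(t, angle, min_segment_s = 1,
                                 min_amplitude_deg = 1) {
  # centre on the midrange: with two sustained plateaus the midrange sits
  # between them regardless of their relative durations
  z <- angle - (max(angle) + min(angle)) / 2
  s <- sign(z)
  s[abs(z) < min_amplitude_deg / 2] <- 0
  nz <- which(s != 0)
  if (!length(nz)) return(NA_real_)
  first_sign <- s[nz[1]]
  opp <- nz[s[nz] == -first_sign]
  if (!length(opp)) return(NA_real_)
  i_switch <- opp[1]
  pre <- which(s == first_sign & seq_along(s) < i_switch)
  post <- which(s == -first_sign & seq_along(s) >= i_switch)
  dur_pre <- if (length(pre)) t[max(pre)] - t[min(pre)] else 0
  dur_post <- if (length(post)) t[max(post)] - t[min(post)] else 0
  amp_pre <- mean(abs(z[pre]))
  amp_post <- mean(abs(z[post]))
  if (dur_pre < min_segment_s || dur_post < min_segment_s ||
      amp_pre < min_amplitude_deg || amp_post < min_amplitude_deg) {
    return(NA_real_)
  }
  # boundary between the last pre-switch and first post-switch sample
  (t[max(pre)] + t[i_switch]) / 2
}
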