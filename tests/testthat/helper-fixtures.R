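# Shared fixture builders (all generated in code, nothing on disk).

# a face68 frame from the symmetric template, optionally modified
make_face_frame <- function(t = 0, modify = NULL, conf = 1,
                            frame_size = c(800, 450)) {
  pts <- mgcekit:::face_template()
  if (!is.null(modify)) pts <- modify(pts)
  landmark_frame(t, pts, "face68", conf = conf, frame_size = frame_size)
}

# a body33 frame with explicit shoulder/elbow placement
make_body_frame <- function(t = 0, shoulders = NULL, elbows = NULL,
                            hips = NULL, frame_size = c(800, 450)) {
  pts <- mgcekit:::body_template()
  if (!is.null(shoulders)) { pts[12, ] <- shoulders$left; pts[13, ] <- shoulders$right }
  if (!is.null(elbows)) { pts[14, ] <- elbows$left; pts[15, ] <- elbows$right }
  if (!is.null(hips)) { pts[24, ] <- hips$left; pts[25, ] <- hips$right }
  landmark_frame(t, pts, "body33", frame_size = frame_size)
}

make_body_stream <- function(frames) landmark_stream(frames)

# flat-lidded analytic eye geometry for arithmetic checks
flat_eye_geometry <- function(upper_y = 4, lower_y = 16, pupil = c(20, 10),
                              iris = c(15, 25)) {
  eye_geometry(
    pupil_center = pupil, iris_x_left = iris[1], iris_x_right = iris[2],
    iris_bottom_y = pupil[2] + (iris[2] - iris[1]) / 2,
    upper_lid = c(upper_y, 0, 0), lower_lid = c(lower_y, 0, 0),
    quality = "ok"
  )
}

# a ptosis_series data.frame directly from numeric measures
measures_series <- function(t, d_lid_pupil, d_lid_lid = d_lid_pupil + 6,
                            area = d_lid_pupil * 10, mask = TRUE) {
  structure(
    data.frame(t = t, d_lid_pupil = d_lid_pupil, d_lid_lid = d_lid_lid,
               area = area, mask = mask),
    class = c("ptosis_series", "data.frame"), normalized = FALSE
  )
}

sine_track <- function(f0, amp, dur, fs = 48000) {
  audio_track(amp * sin(2 * pi * f0 * (0:(fs * dur - 1)) / fs), fs)
}
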