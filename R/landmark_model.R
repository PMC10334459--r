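#' Landmark schemas and index constants
#'
#' The toolbox consumes two landmark schemas: a 68-point face schema
#' (1-based indices, as conventional for that model) and a 33-point
#' body-pose schema (0-based indices, as conventional for that model).
#' Pixel coordinates use the native image convention: origin at the
#' top-left corner, y increasing downward, so "elevation" of a body part
#' corresponds to *decreasing* y.
#'
#' Key index groups (face, 1-based): right-eye hexagon 37-42, left-eye
#' hexagon 43-48, mouth 49-68, mouth corners 49 and 55, upper-lip centre
#' 52, nose base 34, cheek polygon 3-15-13-5. Body (0-based): shoulders
#' 11/12, elbows 13/14, hips 23/24.
#'
#' @format A named list of integer index vectors.
#' @export
mgce_landmarks <- list(
  face68 = list(
    n = 68L, base = 1L,
    eye_right = 37:42, eye_left = 43:48,
    eye_corners_right = c(37L, 40L), eye_corners_left = c(43L, 46L),
    mouth = 49:68, mouth_corners = c(49L, 55L),
    upper_lip_center = 52L, nose_base = 34L,
    cheek_polygon = c(3L, 15L, 13L, 5L)
  ),
  body33 = list(
    n = 33L, base = 0L,
    shoulder_left = 11L, shoulder_right = 12L,
    elbow_left = 13L, elbow_right = 14L,
    hip_left = 23L, hip_right = 24L
  )
)

#' Look up a body landmark by its 0-based schema index
#'
#' @param frame a `landmark_frame` with schema `body33`
#' @param idx 0-based index (or vector) per the 33-point pose schema
#' @return numeric matrix of coordinates, one row per index
#' @export
body_point <- function(frame, idx) {
  frame$points[idx + 1L, , drop = FALSE]
}

#' Look up a face landmark by its 1-based schema index
#'
#' @param frame a `landmark_frame` with schema `face68`
#' @param idx 1-based index (or vector) per the 68-point face schema
#' @return numeric matrix of coordinates, one row per index
#' @export
face_point <- function(frame, idx) {
  frame$points[idx, , drop = FALSE]
}

schema_n_points <- function(schema) {
  switch(schema,
    face68 = 68L,
    body33 = 33L,
    abort_mgce(sprintf("unknown landmark schema '%s'", schema), "mgce_schema_error")
  )
}

#' Construct a single time-stamped landmark frame
#'
#' @param t time in seconds from exercise start
#' @param points numeric matrix (68 x 2 for `face68`, 33 x 2 for `body33`)
#'   of pixel coordinates, origin top-left, y down
#' @param schema `"face68"` or `"body33"`
#' @param conf detector confidence in `[0, 1]`
#' @param frame_size `c(width, height)` of the source frame in pixels
#' @return an object of class `landmark_frame`
#' @export
landmark_frame <- function(t, points, schema, conf = 1, frame_size = c(1280L, 720L)) {
  points <- as.matrix(points)
  n <- schema_n_points(schema)
  if (nrow(points) != n || ncol(points) != 2L) {
    abort_mgce(
      sprintf("schema '%s' requires %d points, got %d", schema, n, nrow(points)),
      "mgce_schema_error"
    )
  }
  if (!all(is.finite(points))) {
    abort_mgce("landmark coordinates must all be finite", "mgce_schema_error")
  }
  if (!is_finite_num(conf) || conf < 0 || conf > 1) {
    abort_mgce("confidence must be a number in [0, 1]", "mgce_schema_error")
  }
  structure(
    list(t = as.numeric(t), points = unname(points), schema = schema,
         conf = as.numeric(conf), frame_size = as.numeric(frame_size)),
    class = "landmark_frame"
  )
}

#' Construct a landmark stream from a list of frames
#'
#' Frames must share one schema and have strictly increasing timestamps.
#' Frames whose confidence falls below `conf_floor` are *flagged* (kept in
#' the stream, excluded from downstream fits), never dropped.
#'
#' @param frames list of [landmark_frame()] objects
#' @param conf_floor confidence below which a frame is flagged (default 0.5)
#' @return an object of class `landmark_stream` with fields `schema`,
#'   `frames`, `fps` (inferred from median timestamp spacing) and logical
#'   `flagged` per frame
#' @export
landmark_stream <- function(frames, conf_floor = 0.5) {
  if (!length(frames)) abort_mgce("empty landmark stream", "mgce_schema_error")
  schemas <- unique(vapply(frames, function(f) f$schema, character(1)))
  if (length(schemas) != 1L) {
    abort_mgce("a stream must carry a single landmark schema", "mgce_schema_error")
  }
  frames <- unname(frames)
  t <- vapply(frames, function(f) f$t, numeric(1))
  if (length(t) > 1L && any(diff(t) <= 0)) {
    abort_mgce("timestamps must be strictly increasing", "mgce_schema_error")
  }
  fps <- if (length(t) > 1L) 1 / stats::median(diff(t)) else NA_real_
  flagged <- vapply(frames, function(f) f$conf < conf_floor, logical(1))
  structure(
    list(schema = schemas, frames = frames, fps = fps,
         t = t, flagged = flagged, conf_floor = conf_floor),
    class = "landmark_stream"
  )
}

#' @export
print.landmark_stream <- function(x, ...) {
  cat(sprintf(
    "<landmark_stream> schema=%s frames=%d fps=%.3g flagged=%d span=[%.3g, %.3g] s\n",
    x$schema, length(x$frames), x$fps, sum(x$flagged),
    x$t[1], x$t[length(x$t)]
  ))
  invisible(x)
}

#' @export
length.landmark_stream <- function(x) length(x$frames)

#' Read a landmark stream from CSV or JSONL
#'
#' CSV columns (header required): `t, schema, idx, x, y, conf`, one row per
#' landmark, `idx` in the schema's native base (1-based for `face68`,
#' 0-based for `body33`). JSONL: one frame per line, e.g.
#' `{"t": 0.0, "schema": "face68", "points": [[x, y], ...], "conf": 0.98}`.
#' Format is chosen by file extension (`.csv` vs `.jsonl`/`.json`).
#'
#' @param path file path
#' @param schema expected schema id (`"face68"` or `"body33"`)
#' @param conf_floor confidence flagging floor, see [landmark_stream()]
#' @return a validated [landmark_stream()]
#' @export
load_landmark_stream <- function(path, schema, conf_floor = 0.5) {
  if (!file.exists(path)) {
    abort_mgce(sprintf("landmark file not found: %s", path), "mgce_input_error")
  }
  n <- schema_n_points(schema)
  base <- mgce_landmarks[[schema]]$base
  ext <- tolower(tools::file_ext(path))
  frames <- if (ext == "csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e) abort_mgce(
        sprintf("cannot parse %s: %s", path, conditionMessage(e)), "mgce_parse_error")
    )
    need <- c("t", "schema", "idx", "x", "y", "conf")
    if (!all(need %in% names(df))) {
      abort_mgce(sprintf("CSV must have columns %s", paste(need, collapse = ", ")),
                 "mgce_parse_error")
    }
    bad <- which(!is.finite(df$x) | !is.finite(df$y))
    if (length(bad)) {
      abort_mgce(sprintf("non-finite coordinate at data line %d", bad[1]),
                 "mgce_parse_error")
    }
    lapply(split(df, df$t), function(fr) {
      if (nrow(fr) != n) {
        abort_mgce(
          sprintf("frame at t=%.4g has %d points; schema '%s' requires %d",
                  fr$t[1], nrow(fr), schema, n),
          "mgce_schema_error"
        )
      }
      fr <- fr[order(fr$idx), ]
      if (!identical(as.integer(fr$idx), seq_len(n) - 1L + base)) {
        abort_mgce(sprintf("frame at t=%.4g has malformed indices", fr$t[1]),
                   "mgce_schema_error")
      }
      landmark_frame(fr$t[1], cbind(fr$x, fr$y), schema, conf = min(fr$conf))
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      rec <- tryCatch(
        jsonlite::fromJSON(lines[i], simplifyMatrix = TRUE),
        error = function(e) abort_mgce(
          sprintf("malformed JSONL at line %d: %s", i, conditionMessage(e)),
          "mgce_parse_error")
      )
      pts <- as.matrix(rec$points)
      if (nrow(pts) != n) {
        abort_mgce(
          sprintf("line %d has %d points; schema '%s' requires %d",
                  i, nrow(pts), schema, n),
          "mgce_schema_error"
        )
      }
      landmark_frame(rec$t, pts, schema,
                     conf = if (is.null(rec$conf)) 1 else rec$conf)
    })
  }
  frames <- frames[order(vapply(frames, function(f) f$t, numeric(1)))]
  landmark_stream(frames, conf_floor = conf_floor)
}

#' Write a landmark stream to CSV or JSONL
#'
#' Inverse of [load_landmark_stream()]; `load(write(s))` is the identity on
#' valid streams (coordinates serialized at full precision).
#'
#' @param stream a [landmark_stream()]
#' @param path destination; `.csv` or `.jsonl` selects the format
#' @return `path`, invisibly
#' @export
write_landmark_stream <- function(stream, path) {
  ext <- tolower(tools::file_ext(path))
  base <- mgce_landmarks[[stream$schema]]$base
  n <- schema_n_points(stream$schema)
  if (ext == "csv") {
    rows <- lapply(stream$frames, function(f) {
      data.frame(
        t = f$t, schema = f$schema, idx = seq_len(n) - 1L + base,
        x = f$points[, 1], y = f$points[, 2], conf = f$conf
      )
    })
    df <- do.call(rbind, rows)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (f in stream$frames) {
      writeLines(jsonlite::toJSON(
        list(t = f$t, schema = f$schema,
             points = f$points, conf = f$conf),
        auto_unbox = TRUE, digits = NA
      ), con)
    }
  }
  invisible(path)
}

#' Construct a region of interest
#'
#' @param kind one of `eye_left`, `eye_right`, `cheek_left`, `cheek_right`,
#'   `cheek_both`, `mouth`
#' @param polygon n x 2 matrix of vertices (a box is its 4 corners)
#' @param t source frame time, seconds
#' @return object of class `mgce_roi` with `kind`, `polygon`, `box`
#'   (xmin, ymin, xmax, ymax) and `t`
#' @export
mgce_roi <- function(kind, polygon, t = NA_real_) {
  polygon <- as.matrix(polygon)
  if (polygon_area(polygon) <= 0) {
    abort_mgce(sprintf("ROI '%s' has zero area", kind), "mgce_geometry_error")
  }
  structure(
    list(kind = kind, polygon = unname(polygon),
         box = c(
           xmin = min(polygon[, 1]), ymin = min(polygon[, 2]),
           xmax = max(polygon[, 1]), ymax = max(polygon[, 2])
         ),
         t = t),
    class = "mgce_roi"
  )
}

box_to_polygon <- function(b) {
  rbind(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]), c(b[1], b[4]))
}

#' Eye regions of interest from a face frame
#'
#' Each ROI is the axis-aligned bounding box of the six eye-hexagon
#' landmarks, expanded by `pad` pixels on every side and clipped to the
#' frame bounds. The refinement stage of the eye segmentation runs inside
#' these boxes.
#'
#' @param face a `face68` [landmark_frame()]
#' @param pad padding in pixels (each side)
#' @return named list `right`, `left` of [mgce_roi()] boxes
#' @export
eye_rois <- function(face, pad = 4) {
  stopifnot(face$schema == "face68")
  w <- face$frame_size[1]; h <- face$frame_size[2]
  one <- function(idx, kind) {
    p <- face_point(face, idx)
    if (!all(is.finite(p))) abort_mgce("eye landmarks not finite", "mgce_geometry_error")
    b <- c(min(p[, 1]) - pad, min(p[, 2]) - pad, max(p[, 1]) + pad, max(p[, 2]) + pad)
    b <- c(max(b[1], 0), max(b[2], 0), min(b[3], w), min(b[4], h))
    if (b[3] - b[1] <= 0 || b[4] - b[2] <= 0) {
      abort_mgce(sprintf("degenerate %s box", kind), "mgce_geometry_error")
    }
    mgce_roi(kind, box_to_polygon(b), t = face$t)
  }
  list(
    right = one(mgce_landmarks$face68$eye_right, "eye_right"),
    left = one(mgce_landmarks$face68$eye_left, "eye_left")
  )
}

#' Cheek region of interest from a face frame
#'
#' The cheek-puff ROI is the quadrilateral through jaw landmarks
#' 3 - 15 - 13 - 5. For the one-sided tongue-to-cheek exercise the ROI is
#' restricted to one half of that polygon, split by the vertical line
#' through its centroid; the half containing landmarks 13/15 is the
#' subject's left cheek.
#'
#' @param face a `face68` [landmark_frame()]
#' @param side `"both"`, `"left"` or `"right"` (subject side)
#' @return an [mgce_roi()] polygon
#' @export
cheek_roi <- function(face, side = c("both", "left", "right")) {
  side <- match.arg(side)
  idx <- mgce_landmarks$face68$cheek_polygon
  quad <- face_point(face, idx)
  if (!all(is.finite(quad))) {
    abort_mgce("cheek polygon landmarks not finite", "mgce_geometry_error")
  }
  # reject a self-intersecting (bow-tie) quadrilateral
  if (segments_intersect(quad[1, ], quad[2, ], quad[3, ], quad[4, ]) ||
      segments_intersect(quad[2, ], quad[3, ], quad[4, ], quad[1, ])) {
    abort_mgce("cheek polygon is self-intersecting", "mgce_geometry_error")
  }
  if (side == "both") return(mgce_roi("cheek_both", quad, t = face$t))
  cx <- mean(quad[, 1])
  # image side of the subject's cheek: landmarks 15/13 carry the subject-left
  left_on_right <- mean(face_point(face, c(15L, 13L))[, 1]) >= cx
  img_side <- if ((side == "left") == left_on_right) "right" else "left"
  half <- clip_polygon_vertical(quad, cx, keep = img_side)
  mgce_roi(paste0("cheek_", side), half, t = face$t)
}

#' Horizontal torso reference line
#'
#' The arm angle is measured against the image-horizontal line through the
#' shoulder midpoint; by definition its direction is the image x-axis, so a
#' tilted shoulder line does not rotate the reference.
#'
#' @param body a `body33` [landmark_frame()]
#' @return list with `y` (line height, px) and `slope` (always 0)
#' @export
torso_horizontal <- function(body) {
  stopifnot(body$schema == "body33")
  sh <- body_point(body, c(mgce_landmarks$body33$shoulder_left,
                           mgce_landmarks$body33$shoulder_right))
  if (!all(is.finite(sh))) {
    abort_mgce("shoulder landmarks missing or not finite", "mgce_input_error")
  }
  list(y = mean(sh[, 2]), slope = 0)
}
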