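# Hybrid eye/lid segmentation for telehealth-resolution eye patches.
#
# Circle-fitting approaches (Hough, integro-differential) are unreliable on
# ~40x20 px eye regions, so the segmenter combines a 2-class intensity
# clustering step (isolating the dark iris+pupil blob) with a local
# vertical-gradient search for the lid boundaries, robust-fitted by
# quadratics. At this resolution pupil and iris are not separable; the
# darkness-weighted centroid of the blob is reported as the pupil centre.

#' An eye-region image patch
#'
#' @param pixels grayscale matrix `[height x width]` in `[0, 1]`, or an
#'   `[height x width x 3]` RGB array; rows are image rows (y down)
#' @param offset `c(x, y)` of the patch origin within the full frame
#' @param side `"left"` or `"right"` (subject side)
#' @return object of class `eye_patch`
#' @export
eye_patch <- function(pixels, offset = c(0, 0), side = c("left", "right")) {
  side <- match.arg(side)
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    # Rec.601 luma
    pixels <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  }
  pixels <- as.matrix(pixels)
  if (!all(is.finite(pixels))) {
    abort_mgce("patch intensities must be finite", "mgce_input_error")
  }
  if (ncol(pixels) < 16L || nrow(pixels) < 8L) {
    abort_mgce(sprintf("patch too small (%dx%d); need at least 16x8 px",
                       ncol(pixels), nrow(pixels)),
               "mgce_input_error")
  }
  structure(list(pixels = pixels, offset = as.numeric(offset), side = side),
            class = "eye_patch")
}

#' Read an eye patch from a PNG file
#'
#' @param path PNG file
#' @inheritParams eye_patch
#' @return an [eye_patch()]
#' @export
read_eye_patch <- function(path, offset = c(0, 0), side = "left") {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_mgce("reading PNG patches requires the 'png' package", "mgce_input_error")
  }
  eye_patch(png::readPNG(path), offset = offset, side = side)
}

#' Per-frame eye geometry
#'
#' Lid curves are quadratics `y = a + b x + c x^2` in patch coordinates
#' (coefficient vectors `c(a, b, c)`); the pixel at row i, column j has its
#' centre at `(j - 0.5, i - 0.5)`.
#'
#' @param pupil_center `c(x, y)`, px
#' @param iris_x_left,iris_x_right vertical iris borders, px
#' @param iris_bottom_y lowest iris point, px
#' @param upper_lid,lower_lid quadratic coefficients `c(a, b, c)`
#' @param quality `"ok"`, `"low_contrast"` or `"closed"`
#' @param offset patch origin in the full frame
#' @param diagnostics optional list of segmentation internals
#' @return object of class `eye_geometry`
#' @export
eye_geometry <- function(pupil_center = c(NA_real_, NA_real_),
                         iris_x_left = NA_real_, iris_x_right = NA_real_,
                         iris_bottom_y = NA_real_,
                         upper_lid = rep(NA_real_, 3),
                         lower_lid = rep(NA_real_, 3),
                         quality = "ok", offset = c(0, 0),
                         diagnostics = list()) {
  structure(
    list(pupil_center = as.numeric(pupil_center),
         iris_x_left = iris_x_left, iris_x_right = iris_x_right,
         iris_bottom_y = iris_bottom_y,
         upper_lid = as.numeric(upper_lid), lower_lid = as.numeric(lower_lid),
         quality = quality, offset = as.numeric(offset),
         diagnostics = diagnostics),
    class = "eye_geometry"
  )
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat(sprintf(
    "<eye_geometry> quality=%s pupil=(%.2f, %.2f) iris x=[%.2f, %.2f]\n",
    x$quality, x$pupil_center[1], x$pupil_center[2],
    x$iris_x_left, x$iris_x_right
  ))
  invisible(x)
}

#' Segmentation configuration
#'
#' @param cluster_method `"otsu"` or `"kmeans"` for the 2-class intensity
#'   split isolating the dark iris/pupil blob
#' @param min_area minimum dark-component area in px^2 (below: eye is
#'   reported closed)
#' @param stretch_quantiles percentile range for contrast normalization
#' @param min_contrast intensity range below which the patch is treated as
#'   contrast-free (closed/blank)
#' @param lid_margin extra rows beyond the blob within which the lid
#'   gradient search runs
#' @param subpixel parabolic sub-pixel refinement of gradient peaks
#' @return list of class `eye_seg_params`
#' @export
eye_seg_params <- function(cluster_method = c("otsu", "kmeans"),
                           min_area = 6, stretch_quantiles = c(0.01, 0.99),
                           min_contrast = 0.05, lid_margin = 2L,
                           subpixel = TRUE) {
  structure(
    list(cluster_method = match.arg(cluster_method), min_area = min_area,
         stretch_quantiles = stretch_quantiles, min_contrast = min_contrast,
         lid_margin = as.integer(lid_margin), subpixel = subpixel),
    class = "eye_seg_params"
  )
}

# robust quadratic fit of y over x with one round of 2*MAD rejection
fit_lid_quadratic <- function(x, y) {
  keep <- is.finite(y)
  if (sum(keep) < 4L) return(rep(NA_real_, 3))
  fit <- stats::lm(y[keep] ~ x[keep] + I(x[keep]^2))
  res <- stats::residuals(fit)
  s <- stats::mad(res)
  if (is.finite(s) && s > 0) {
    inl <- abs(res) <= 2 * s
    if (sum(inl) >= 4L && any(!inl)) {
      fit <- stats::lm(y[keep][inl] ~ x[keep][inl] + I(x[keep][inl]^2))
    }
  }
  cf <- unname(stats::coef(fit))
  if (any(!is.finite(cf))) cf[!is.finite(cf)] <- 0
  cf
}

# parabolic sub-sample refinement of an extremum at index i of v
refine_parabolic <- function(v, i) {
  if (i <= 1L || i >= length(v)) return(0)
  if (anyNA(v[(i - 1L):(i + 1L)])) return(0)
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (abs(denom) < 1e-12) return(0)
  d <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  max(-0.5, min(0.5, d))
}

#' Segment an eye patch into pupil, iris borders and lid curves
#'
#' Pipeline: grayscale + percentile contrast stretch; 2-class intensity
#' clustering (Otsu threshold or 1-D k-means) isolates dark pixels; the
#' largest dark connected component of at least `min_area` px^2 (ties
#' broken toward the patch centre) is taken as the iris+pupil blob; the
#' pupil centre is its darkness-weighted centroid and the iris borders its
#' extreme columns. Lids are located per column as the strongest
#' bright-to-dark (upper) / dark-to-bright (lower) vertical gradient just
#' outside the blob, refined to sub-pixel by parabolic interpolation and
#' robust-fitted by quadratics. On failure the geometry carries a quality
#' flag (`closed`, `low_contrast`) instead of a guess.
#'
#' @param patch an [eye_patch()]
#' @param params an [eye_seg_params()]
#' @return an [eye_geometry()]
#' @export
segment_eye <- function(patch, params = eye_seg_params()) {
  stopifnot(inherits(patch, "eye_patch"))
  img <- patch$pixels
  h <- nrow(img); w <- ncol(img)

  q <- stats::quantile(img, params$stretch_quantiles, names = FALSE)
  if (diff(q) < params$min_contrast) {
    return(eye_geometry(quality = "closed", offset = patch$offset))
  }
  g <- (img - q[1]) / diff(q)
  g[g < 0] <- 0
  g[g > 1] <- 1

  thr <- if (params$cluster_method == "otsu") {
    EBImage::otsu(EBImage::Image(t(g)), range = c(0, 1))
  } else {
    km <- stats::kmeans(as.vector(g), centers = c(min(g), max(g)))
    mean(sort(km$centers))
  }
  mask <- g < thr

  lab <- EBImage::bwlabel(t(mask))  # EBImage uses (x, y) order
  lab <- t(EBImage::imageData(lab))
  n_comp <- max(lab)
  if (n_comp < 1L) {
    return(eye_geometry(quality = "closed", offset = patch$offset))
  }
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  big <- which(areas >= params$min_area)
  if (!length(big)) {
    return(eye_geometry(quality = "closed", offset = patch$offset))
  }
  # largest area; ties broken by centroid distance to the patch centre
  amax <- max(areas[big])
  cand <- big[areas[big] == amax]
  if (length(cand) > 1L) {
    ctr <- c(w / 2, h / 2)
    d2 <- vapply(cand, function(k) {
      ij <- which(lab == k, arr.ind = TRUE)
      sum((c(mean(ij[, 2]) - 0.5, mean(ij[, 1]) - 0.5) - ctr)^2)
    }, numeric(1))
    cand <- cand[which.min(d2)]
  }
  comp <- lab == cand[1]

  ij <- which(comp, arr.ind = TRUE)
  px_x <- ij[, 2] - 0.5
  px_y <- ij[, 1] - 0.5
  wgt <- 1 - g[comp]  # darkness weight
  wgt <- wgt / sum(wgt)
  pupil <- c(sum(wgt * px_x), sum(wgt * px_y))

  cols <- sort(unique(ij[, 2]))
  iris_x_left <- min(px_x); iris_x_right <- max(px_x)
  iris_bottom_y <- max(px_y)

  # per-column lid search on the lightly smoothed image
  gs <- g
  if (h >= 3L) {
    gs <- (rbind(g[1, , drop = FALSE], g[-h, , drop = FALSE]) + g +
             rbind(g[-1, , drop = FALSE], g[h, , drop = FALSE])) / 3
  }
  m <- params$lid_margin
  up_y <- rep(NA_real_, length(cols))
  lo_y <- rep(NA_real_, length(cols))
  for (ci in seq_along(cols)) {
    j <- cols[ci]
    rows_in <- ij[ij[, 2] == j, 1]
    top <- min(rows_in); bot <- max(rows_in)
    grad <- c(NA, diff(gs[, j]))  # grad[i] ~ d I / d y between i-1 and i
    hi <- min(h, top + m)
    if (hi >= 2L) {
      seg <- grad[2:hi]
      i0 <- which.min(seg) + 1L  # most negative: bright -> dark downward
      dy <- if (params$subpixel) refine_parabolic(-grad, i0) else 0
      up_y[ci] <- (i0 - 1) + dy  # boundary between rows i0-1 and i0
    }
    lo0 <- max(2L, bot - m)
    if (lo0 <= h) {
      seg <- grad[lo0:h]
      i0 <- which.max(seg) + lo0 - 1L
      dy <- if (params$subpixel) refine_parabolic(grad, i0) else 0
      lo_y[ci] <- (i0 - 1) + dy
    }
  }
  xc <- cols - 0.5
  up_cf <- fit_lid_quadratic(xc, up_y)
  lo_cf <- fit_lid_quadratic(xc, lo_y)

  touches <- c(
    top = any(ij[, 1] == 1L), bottom = any(ij[, 1] == h),
    left = any(ij[, 2] == 1L), right = any(ij[, 2] == w)
  )
  eye_geometry(
    pupil_center = pupil,
    iris_x_left = iris_x_left, iris_x_right = iris_x_right,
    iris_bottom_y = iris_bottom_y,
    upper_lid = up_cf, lower_lid = lo_cf,
    quality = "ok", offset = patch$offset,
    diagnostics = list(
      threshold = thr, comp_area = amax, touches = touches,
      contrast = unname(diff(q)), columns = xc,
      upper_lid_samples = up_y, lower_lid_samples = lo_y
    )
  )
}

#' The three per-frame eye opening measures
#'
#' At the pupil column: the vertical lid-to-lid distance and the vertical
#' distance from the upper-lid curve down to the pupil centre; plus the
#' opening area between the two lid curves integrated over the iris span.
#'
#' @param geom an [eye_geometry()] with `quality == "ok"`
#' @return named numeric: `d_lid_lid` (px), `area` (px^2), `d_lid_pupil` (px)
#' @export
eye_measures <- function(geom) {
  stopifnot(inherits(geom, "eye_geometry"))
  if (!identical(geom$quality, "ok")) {
    abort_mgce(sprintf("measures unavailable: segmentation quality is '%s'",
                       geom$quality), "mgce_quality_error")
  }
  px <- geom$pupil_center[1]
  yu <- polyval2(geom$upper_lid, px)
  yl <- polyval2(geom$lower_lid, px)
  # opening area: integral of (lower - upper) over the iris span
  dcf <- geom$lower_lid - geom$upper_lid
  x1 <- geom$iris_x_left; x2 <- geom$iris_x_right
  anti <- function(x) dcf[1] * x + dcf[2] * x^2 / 2 + dcf[3] * x^3 / 3
  c(d_lid_lid = yl - yu,
    area = anti(x2) - anti(x1),
    d_lid_pupil = geom$pupil_center[2] - yu)
}

#' Quality report for a segmentation result
#'
#' Checks the geometric invariants (lid ordering, pupil inside the patch,
#' iris border ordering), the patch contrast, the dark-component size, and
#' whether the component spills across all four patch borders. Always
#' returns a report, never throws.
#'
#' @param geom an [eye_geometry()]
#' @param patch the [eye_patch()] it came from (optional; enables bounds
#'   and contrast checks)
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed checks, empty when passing)
#' @export
validate_segmentation <- function(geom, patch = NULL) {
  reasons <- character(0)
  if (!identical(geom$quality, "ok")) {
    reasons <- c(reasons, sprintf("quality flag: %s", geom$quality))
    return(list(pass = FALSE, reasons = reasons))
  }
  px <- geom$pupil_center[1]
  if (all(is.finite(geom$upper_lid)) && all(is.finite(geom$lower_lid))) {
    if (polyval2(geom$lower_lid, px) < polyval2(geom$upper_lid, px)) {
      reasons <- c(reasons, "lid-order violation: upper lid below lower lid")
    }
  } else {
    reasons <- c(reasons, "lid curves undefined")
  }
  if (!is.finite(geom$iris_x_left) || !is.finite(geom$iris_x_right) ||
      geom$iris_x_left >= geom$iris_x_right) {
    reasons <- c(reasons, "iris borders not ordered")
  }
  if (!is.null(patch)) {
    h <- nrow(patch$pixels); w <- ncol(patch$pixels)
    if (!all(is.finite(geom$pupil_center)) ||
        px < 0 || px > w ||
        geom$pupil_center[2] < 0 || geom$pupil_center[2] > h) {
      reasons <- c(reasons, "pupil centre outside patch")
    }
  }
  d <- geom$diagnostics
  if (!is.null(d$contrast) && d$contrast < 0.1) {
    reasons <- c(reasons, "low contrast")
  }
  if (!is.null(d$touches) && all(d$touches)) {
    reasons <- c(reasons, "spill: dark component touches all four borders")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Write a debug overlay of a segmentation to PNG
#'
#' Marks the pupil centre, iris borders and fitted lid curves on the patch
#' for visual QA.
#'
#' @param geom an [eye_geometry()]
#' @param patch the source [eye_patch()]
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
write_segmentation_overlay <- function(geom, patch, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort_mgce("overlay output requires the 'png' package", "mgce_input_error")
  }
  img <- patch$pixels
  rgb <- array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
  put <- function(x, y, ch) {
    i <- round(y + 0.5); j <- round(x + 0.5)
    if (i >= 1 && i <= nrow(img) && j >= 1 && j <= ncol(img)) {
      rgb[i, j, ] <<- 0; rgb[i, j, ch] <<- 1
    }
  }
  if (identical(geom$quality, "ok")) {
    put(geom$pupil_center[1], geom$pupil_center[2], 1)
    for (x in seq(0.5, ncol(img) - 0.5)) {
      if (all(is.finite(geom$upper_lid))) put(x, polyval2(geom$upper_lid, x), 2)
      if (all(is.finite(geom$lower_lid))) put(x, polyval2(geom$lower_lid, x), 3)
    }
  }
  png::writePNG(pmin(1, pmax(0, rgb)), path)
  invisible(path)
}

#' Segmentation accuracy over a randomized synthetic batch
#'
#' Renders `n` telehealth-resolution eye patches with randomized pupil,
#' iris and lid geometry (seeded), runs [segment_eye()], and reports the
#' per-patch Euclidean pupil-centre error and the absolute
#' lid-to-pupil-distance error against the analytic ground truth.
#'
#' @param n number of patches (>= 1)
#' @param seed RNG seed for the batch
#' @param noise_sigma pixel noise sd (default 0.05)
#' @param params an [eye_seg_params()]
#' @return data.frame with columns `pupil_error`, `d_lid_pupil_error`,
#'   `quality`
#' @export
segmentation_accuracy_batch <- function(n = 50L, seed = 1L,
                                        noise_sigma = 0.05,
                                        params = eye_seg_params()) {
  draws <- with_seed(seed, {
    data.frame(
      px = stats::runif(n, 16, 24), py = stats::runif(n, 8, 12),
      iris = stats::runif(n, 4, 6), d0 = stats::runif(n, 3, 6),
      lower = stats::runif(n, 5, 7),
      scene_seed = sample.int(1e6, n)
    )
  })
  out <- data.frame(pupil_error = rep(NA_real_, n),
                    d_lid_pupil_error = NA_real_,
                    quality = NA_character_)
  for (i in seq_len(n)) {
    sp <- eye_scene_params(
      pupil_center = c(draws$px[i], draws$py[i]),
      iris_radius = draws$iris[i], lid_pupil_distance = draws$d0[i],
      lower_lid_offset = draws$lower[i],
      noise_sigma = noise_sigma, seed = draws$scene_seed[i]
    )
    r <- render_eye_sequence(sp, 1L)
    g <- segment_eye(r$frames[[1]], params)
    out$quality[i] <- g$quality
    if (identical(g$quality, "ok")) {
      out$pupil_error[i] <- sqrt(sum((g$pupil_center - sp$pupil_center)^2))
      m <- eye_measures(g); mt <- eye_measures(r$truth[[1]])
      out$d_lid_pupil_error[i] <- abs(m[["d_lid_pupil"]] - mt[["d_lid_pupil"]])
    }
  }
  out
}
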