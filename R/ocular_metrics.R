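# Ptosis and ocular-alignment exercise metrics.
#
# The ptosis exercise (sustained upgaze, 60 s) is summarized by a linear
# least-squares fit of the lid-to-pupil distance over time; its percent
# decay over the window and the slope significance quantify lid fatigue.
# The diplopia exercise (sustained lateral gaze) tracks the barycentric
# coordinate of the inner iris border between the eye corners for each eye;
# divergence of the two coordinates from their baseline offset indicates
# ocular misalignment.

#' Assemble a ptosis time series from per-frame eye geometry
#'
#' @param geoms list of [eye_geometry()] (one per frame)
#' @param times frame times, seconds
#' @param min_frames minimum usable frames required (default 10)
#' @param min_span_s minimum time span of usable frames, seconds (default 30)
#' @param normalize divide each measure by the mean of its first 5 usable
#'   frames (baseline-relative series)
#' @return data.frame of class `ptosis_series` with columns `t`,
#'   `d_lid_pupil`, `d_lid_lid`, `area`, `mask` (TRUE = usable)
#' @export
ptosis_series <- function(geoms, times, min_frames = 10L, min_span_s = 30,
                          normalize = FALSE) {
  stopifnot(length(geoms) == length(times))
  ok <- vapply(geoms, function(g) identical(g$quality, "ok"), logical(1))
  meas <- matrix(NA_real_, length(geoms), 3,
                 dimnames = list(NULL, c("d_lid_lid", "area", "d_lid_pupil")))
  for (i in which(ok)) meas[i, ] <- eye_measures(geoms[[i]])
  usable <- ok & stats::complete.cases(meas)
  if (sum(usable) < min_frames ||
      (sum(usable) > 0 && diff(range(times[usable])) < min_span_s)) {
    abort_mgce(
      sprintf("insufficient data: %d usable frames spanning %.1f s (need >= %d over >= %.0f s)",
              sum(usable),
              if (any(usable)) diff(range(times[usable])) else 0,
              min_frames, min_span_s),
      "mgce_insufficient_data"
    )
  }
  df <- data.frame(
    t = times,
    d_lid_pupil = meas[, "d_lid_pupil"],
    d_lid_lid = meas[, "d_lid_lid"],
    area = meas[, "area"],
    mask = usable
  )
  if (normalize) {
    first5 <- utils::head(which(usable), 5L)
    for (col in c("d_lid_pupil", "d_lid_lid", "area")) {
      df[[col]] <- df[[col]] / mean(df[[col]][first5])
    }
  }
  structure(df, class = c("ptosis_series", "data.frame"),
            normalized = normalize)
}

#' Linear decay fit of a ptosis measure
#'
#' Ordinary least squares of the chosen measure against time on unmasked
#' points. `percent_decay` is `100 * (fit(t0) - fit(t1)) / fit(t0)` over
#' the fitted window; the p-value is the standard two-sided t-test of
#' slope = 0.
#'
#' @param series a [ptosis_series()]
#' @param measure `"d_lid_pupil"` (default), `"d_lid_lid"` or `"area"`
#' @return object of class `decay_fit` with `slope` (px/s), `intercept`,
#'   `percent_decay`, `p_value`, `window`
#' @export
fit_linear_decay <- function(series,
                             measure = c("d_lid_pupil", "d_lid_lid", "area")) {
  measure <- match.arg(measure)
  t <- series$t[series$mask]
  y <- series[[measure]][series$mask]
  f <- ols_slope(t, y)
  t0 <- min(t); t1 <- max(t)
  y0 <- f$intercept + f$slope * t0
  y1 <- f$intercept + f$slope * t1
  structure(
    list(measure = measure, slope = f$slope, intercept = f$intercept,
         percent_decay = 100 * (y0 - y1) / y0,
         p_value = f$p_value, window = c(t0, t1)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %s: slope %.4g px/s, decay %.2f%% over [%.1f, %.1f] s (p = %.3g)\n",
    x$measure, x$slope, x$percent_decay, x$window[1], x$window[2], x$p_value
  ))
  invisible(x)
}

# barycentric coordinate of the inner iris border between the eye corners
barycentric_coord <- function(geom, corner_inner_x, corner_outer_x) {
  span <- corner_outer_x - corner_inner_x
  if (abs(span) < 4) {
    abort_mgce("eye-corner span under 4 px", "mgce_geometry_error")
  }
  # the iris border nearer the inner corner is the "most inner" border
  borders <- c(geom$iris_x_left, geom$iris_x_right)
  inner <- borders[which.min(abs(borders - corner_inner_x))]
  b <- (inner - corner_inner_x) / span
  max(0, min(1, b))
}

#' Ocular alignment series from paired eye geometries
#'
#' For each frame and eye, the inner iris border is expressed as a
#' barycentric coordinate `b` in `[0, 1]` between the inner and outer eye
#' corner; misalignment is the absolute deviation of `b_left - b_right`
#' from its baseline offset (median over the first `baseline_s` seconds).
#'
#' @param left_geoms,right_geoms lists of [eye_geometry()] on common frames
#' @param times frame times, seconds
#' @param corners_left,corners_right `c(inner_x, outer_x)` corner positions
#'   in the same (patch) coordinates as the geometries, per eye; either a
#'   length-2 vector (static) or an n x 2 matrix
#' @param baseline_s baseline window for the offset, seconds (default 2)
#' @return data.frame of class `alignment_series` with columns `t`,
#'   `b_left`, `b_right`, `misalignment`
#' @export
alignment_series <- function(left_geoms, right_geoms, times,
                             corners_left, corners_right, baseline_s = 2) {
  n <- length(times)
  stopifnot(length(left_geoms) == n, length(right_geoms) == n)
  as_mat <- function(cc) {
    if (is.matrix(cc)) cc else matrix(rep(cc, each = n), n, 2)
  }
  cl <- as_mat(corners_left); cr <- as_mat(corners_right)
  ok <- vapply(seq_len(n), function(i) {
    identical(left_geoms[[i]]$quality, "ok") &&
      identical(right_geoms[[i]]$quality, "ok")
  }, logical(1))
  if (!any(ok)) abort_mgce("no frames with both eyes segmented", "mgce_input_error")
  b_l <- rep(NA_real_, n); b_r <- rep(NA_real_, n)
  for (i in which(ok)) {
    b_l[i] <- barycentric_coord(left_geoms[[i]], cl[i, 1], cl[i, 2])
    b_r[i] <- barycentric_coord(right_geoms[[i]], cr[i, 1], cr[i, 2])
  }
  delta <- b_l - b_r
  base_idx <- which(ok & times <= times[ok][1] + baseline_s)
  offset <- stats::median(delta[base_idx], na.rm = TRUE)
  structure(
    data.frame(t = times, b_left = b_l, b_right = b_r,
               misalignment = abs(delta - offset)),
    class = c("alignment_series", "data.frame"),
    baseline_offset = offset
  )
}

#' Summary of an alignment series
#'
#' @param series an [alignment_series()]
#' @param threshold misalignment above which the gaze is flagged unsteady
#'   (barycentric units, default 0.1)
#' @param min_span_s minimum data span required, seconds (default 10)
#' @return list with `max_misalignment`, `drift_slope` (1/s, OLS on the
#'   misalignment), `steady` (logical)
#' @export
alignment_summary <- function(series, threshold = 0.1, min_span_s = 10) {
  ok <- is.finite(series$misalignment)
  if (diff(range(series$t[ok])) < min_span_s) {
    abort_mgce(sprintf("alignment summary needs >= %.0f s of data", min_span_s),
               "mgce_insufficient_data")
  }
  f <- ols_slope(series$t[ok], series$misalignment[ok])
  mx <- max(series$misalignment[ok])
  list(max_misalignment = mx, drift_slope = f$slope, steady = mx < threshold)
}

#' Optional exploratory fit: lid relaxation time toward equilibrium
#'
#' Exponential relaxation `d(t) = d_inf + (d_0 - d_inf) exp(-t / tau)`
#' fitted by nonlinear least squares; `tau` is the time to cover
#' `1 - e^-1` of the gap to the asymptote. This summary is exploratory:
#' it is not part of the core examination's metric set.
#'
#' @param series a [ptosis_series()]
#' @param measure which measure to fit
#' @return list with `tau_s`, `d0`, `d_inf`, `converged`
#' @export
fit_relaxation_time <- function(series, measure = "d_lid_pupil") {
  t <- series$t[series$mask]; y <- series[[measure]][series$mask]
  t <- t - t[1]
  fit <- tryCatch(
    stats::nls(y ~ dinf + (d0 - dinf) * exp(-t / tau),
               start = list(dinf = min(y), d0 = y[1],
                            tau = max(diff(range(t)) / 3, 1e-3)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(list(tau_s = NA_real_, d0 = NA_real_,
                                d_inf = NA_real_, converged = FALSE))
  cf <- stats::coef(fit)
  list(tau_s = unname(cf["tau"]), d0 = unname(cf["d0"]),
       d_inf = unname(cf["dinf"]), converged = fit$convInfo$isConv)
}

#' Export a metric series to CSV
#'
#' @param series any of the toolbox's series data.frames
#' @param path destination CSV
#' @return `path`, invisibly
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
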