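# Internal helpers: classed conditions and small planar-geometry primitives.

abort_mgce <- function(msg, class) {
  stop(structure(
    class = c(class, "mgce_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

#' @noRd
polygon_area <- function(xy) {
  # shoelace; positive regardless of orientation
  x <- xy[, 1]; y <- xy[, 2]
  n <- nrow(xy)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

segments_intersect <- function(p1, p2, p3, p4) {
  # proper intersection test for open segments p1-p2 and p3-p4
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Clip a convex/simple polygon by a vertical half-plane (Sutherland-Hodgman)
#' @param xy polygon vertices (n x 2)
#' @param x0 line position
#' @param keep "left" keeps x <= x0, "right" keeps x >= x0
#' @noRd
clip_polygon_vertical <- function(xy, x0, keep = c("left", "right")) {
  keep <- match.arg(keep)
  inside <- if (keep == "left") function(p) p[1] <= x0 else function(p) p[1] >= x0
  n <- nrow(xy)
  out <- list()
  for (i in seq_len(n)) {
    a <- xy[i, ]
    b <- xy[if (i == n) 1L else i + 1L, ]
    ain <- inside(a); bin <- inside(b)
    if (ain) out[[length(out) + 1L]] <- a
    if (xor(ain, bin)) {
      tt <- (x0 - a[1]) / (b[1] - a[1])
      out[[length(out) + 1L]] <- c(x0, a[2] + tt * (b[2] - a[2]))
    }
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, out)
}

# evaluate a quadratic given coefficients c(a, b, c): a + b x + c x^2
polyval2 <- function(cf, x) cf[1] + cf[2] * x + cf[3] * x^2

# run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ordinary least squares y ~ t returning slope/intercept/p-value of the slope
ols_slope <- function(t, y) {
  if (length(unique(t)) < 2L) {
    abort_mgce("cannot fit a trend: no variation in time", "mgce_fit_error")
  }
  fit <- stats::lm(y ~ t)
  # exact synthetic series trip summary.lm's perfect-fit warning; the
  # degenerate p-value is handled explicitly below
  cf <- suppressWarnings(summary(fit))$coefficients
  p <- if (nrow(cf) >= 2L && ncol(cf) >= 4L) cf["t", 4] else NA_real_
  # an exactly constant series has zero residual variance: slope 0 is then
  # certain, not significant
  if (!is.finite(p)) p <- if (abs(stats::coef(fit)[2]) < 1e-12) 1 else 0
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    p_value = unname(p)
  )
}
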