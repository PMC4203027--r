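#' Piecewise cubic Hermite coefficient curve
#'
#' Builds a dimensionless moment-coefficient curve `C(angle)` from knots that
#' specify the angle (degrees), the coefficient value, and the local slope in
#' rad^-1. Between knots the curve is the cubic Hermite interpolant, so the
#' value *and* the derivative at every knot are reproduced exactly; beyond the
#' first/last knot the curve continues linearly with the end slope. Exact knot
#' slopes are the point of this primitive: parameter-recovery tests can assert
#' against analytic ground truth instead of a numerically fitted spline.
#'
#' @param angle_deg strictly increasing knot angles, degrees.
#' @param value coefficient value at each knot (dimensionless).
#' @param slope_per_rad derivative dC/dangle at each knot, per radian.
#' @return an object of class `hermite_curve`.
#' @seealso [curve_value()], [curve_slope()]
#' @export
#' @examples
#' cv <- hermite_curve(c(0, 90), c(0.2, -0.7), c(-0.573, -0.573))
#' curve_value(cv, 20)   # ~0 at the linear zero crossing
#' curve_slope(cv, 50)   # -0.573 everywhere (collinear knots)
hermite_curve <- function(angle_deg, value, slope_per_rad) {
  stopifnot(length(angle_deg) == length(value),
            length(angle_deg) == length(slope_per_rad),
            length(angle_deg) >= 2)
  if (any(!is.finite(angle_deg)) || any(!is.finite(value)) ||
      any(!is.finite(slope_per_rad))) {
    stop("hermite_curve: knots must be finite")
  }
  if (any(diff(angle_deg) <= 0)) {
    stop("hermite_curve: knot angles must be strictly increasing")
  }
  structure(
    list(x = angle_deg * pi / 180, y = value, m = slope_per_rad),
    class = "hermite_curve"
  )
}

hermite_segment <- function(curve, a_rad) {
  n <- length(curve$x)
  i <- findInterval(a_rad, curve$x, all.inside = TRUE)
  h <- curve$x[i + 1] - curve$x[i]
  t <- (a_rad - curve$x[i]) / h
  list(i = i, h = h, t = t)
}

#' Evaluate a Hermite coefficient curve
#'
#' @param curve a [hermite_curve()].
#' @param angle_deg angles in degrees (vectorized).
#' @return coefficient values; linear extrapolation outside the knot range.
#' @export
curve_value <- function(curve, angle_deg) {
  stopifnot(inherits(curve, "hermite_curve"))
  a <- angle_deg * pi / 180
  x <- curve$x; y <- curve$y; m <- curve$m
  n <- length(x)
  seg <- hermite_segment(curve, a)
  t <- seg$t; h <- seg$h; i <- seg$i
  h00 <- 2 * t^3 - 3 * t^2 + 1
  h10 <- t^3 - 2 * t^2 + t
  h01 <- -2 * t^3 + 3 * t^2
  h11 <- t^3 - t^2
  out <- h00 * y[i] + h10 * h * m[i] + h01 * y[i + 1] + h11 * h * m[i + 1]
  lo <- a < x[1]
  hi <- a > x[n]
  out[lo] <- y[1] + m[1] * (a[lo] - x[1])
  out[hi] <- y[n] + m[n] * (a[hi] - x[n])
  out
}

#' Analytic derivative of a Hermite coefficient curve
#'
#' @inheritParams curve_value
#' @return dC/dangle in rad^-1.
#' @export
curve_slope <- function(curve, angle_deg) {
  stopifnot(inherits(curve, "hermite_curve"))
  a <- angle_deg * pi / 180
  x <- curve$x; y <- curve$y; m <- curve$m
  n <- length(x)
  seg <- hermite_segment(curve, a)
  t <- seg$t; h <- seg$h; i <- seg$i
  d00 <- (6 * t^2 - 6 * t) / h
  d10 <- 3 * t^2 - 4 * t + 1
  d01 <- (-6 * t^2 + 6 * t) / h
  d11 <- 3 * t^2 - 2 * t
  out <- d00 * y[i] + d10 * m[i] + d01 * y[i + 1] + d11 * m[i + 1]
  out[a < x[1]] <- m[1]
  out[a > x[n]] <- m[n]
  out
}

#' Zero crossings of a Hermite curve
#'
#' Locates all angles where the curve crosses zero, by sign change on a fine
#' grid refined with [stats::uniroot()]. Used to verify the stored equilibrium
#' angle of a ground-truth object.
#'
#' @inheritParams curve_value
#' @param lo,hi search range, degrees.
#' @return numeric vector of crossing angles (degrees), ascending.
#' @export
curve_zeros <- function(curve, lo = 0, hi = 90) {
  grid <- seq(lo, hi, by = 0.05)
  v <- curve_value(curve, grid)
  zeros <- grid[v == 0]
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(a) curve_value(curve, a),
                   lower = grid[i], upper = grid[i + 1],
                   tol = 1e-10)$root
  }, numeric(1))
  sort(unique(c(zeros, roots)))
}
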