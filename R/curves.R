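#' Discrete planar fiber curves
#'
#' A `bt_curve` is an ordered sequence of `T >= 3` planar points sampled at
#' the uniform parameter `t_i = i/(T-1)` on `[0, 1]`, representing an
#' absolutely continuous curve in the unit-square domain. Consecutive points
#' must be distinct so that the discrete velocity never vanishes.
#'
#' @param points numeric T x 2 matrix (or data frame) of (x, y) coordinates
#'   in domain units on `[0, 1]^2`.
#' @param validate logical; check invariants (default `TRUE`).
#' @return an object of class `bt_curve`: the point matrix with attributes.
#' @examples
#' b <- bt_curve(cbind(seq(0, 1, length.out = 11), 0.5))
#' curve_length(b)
#' @export
bt_curve <- function(points, validate = TRUE) {
  p <- as.matrix(points)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L) stop("curve points must have two columns (x, y)")
  if (validate) {
    if (nrow(p) < 3L) stop("degenerate curve: need at least T = 3 points")
    if (anyNA(p) || any(!is.finite(p))) stop("curve points must be finite")
    if (any(p < -1e-9) || any(p > 1 + 1e-9))
      stop("curve points must lie inside the unit square domain")
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(seg == 0))
      stop("degenerate curve: consecutive points coincide")
  }
  dimnames(p) <- list(NULL, c("x", "y"))
  class(p) <- c("bt_curve", "matrix", "array")
  p
}

#' @export
print.bt_curve <- function(x, ...) {
  cat(sprintf("<bt_curve: %d points, length %.4f>\n", nrow(x), curve_length(x)))
  invisible(x)
}

#' Polyline length of a curve
#' @param curve a [bt_curve()].
#' @return scalar length in domain units.
#' @export
curve_length <- function(curve) {
  p <- unclass(curve)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Discrete derivative fields of a curve
#'
#' Velocity and acceleration by finite-difference stencils on the uniform
#' parameter (central inside, one-sided second-order at the endpoints), the
#' unit tangent field `n = velocity/speed`, and the speeds.
#'
#' @param curve a [bt_curve()].
#' @return list with `velocity`, `acceleration` (T x 2), `tangent` (T x 2,
#'   unit rows), `speed` (length T, positive), and `tangent_dot`, the
#'   parameter derivative of the unit tangent field.
#' @export
curve_derivatives <- function(curve) {
  p <- unclass(bt_curve(curve))
  v <- stencil_deriv(p)
  a <- stencil_deriv2(p)
  sp <- sqrt(rowSums(v^2))
  if (any(sp <= 0)) stop("degenerate curve: zero velocity sample")
  tg <- v / sp
  list(velocity = v, acceleration = a, tangent = tg, speed = sp,
       tangent_dot = stencil_deriv(tg))
}

#' Signed curvature and curvature-flow field
#'
#' Discrete curvature `kappa = (xdot*yddot - ydot*xddot)/speed^3` and the
#' inward unit normal (the 90-degree rotation of the tangent, signed by
#' `kappa` so that `kappa * normal` always points toward the center of the
#' osculating circle). `kappa * normal` is the classical curve-shortening
#' (heat-flow) velocity field; on a circle of radius `r` its magnitude is
#' `1/r`.
#'
#' @param curve a [bt_curve()].
#' @return list with `kappa` (signed, length T), `normal` (T x 2 unit rows,
#'   rotated tangent), and `flow = kappa * normal` (T x 2).
#' @export
curvature <- function(curve) {
  d <- curve_derivatives(curve)
  v <- d$velocity; a <- d$acceleration
  kappa <- (v[, 1] * a[, 2] - v[, 2] * a[, 1]) / d$speed^3
  normal <- rot90_ccw(d$tangent)
  list(kappa = kappa, normal = normal, flow = kappa * normal)
}

#' Resample a curve to uniform arc length
#'
#' Linear interpolation along the polyline at `T_out` equally spaced
#' arc-length stations; endpoints are preserved exactly.
#'
#' @param curve a [bt_curve()].
#' @param n_out number of output points (default: same as input).
#' @return a [bt_curve()] with `n_out` points.
#' @export
resample_curve <- function(curve, n_out = nrow(curve)) {
  p <- unclass(bt_curve(curve))
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  stations <- seq(0, s[length(s)], length.out = n_out)
  ## strictly increasing s is guaranteed by the non-degeneracy invariant
  x <- approx(s, p[, 1], xout = stations)$y
  y <- approx(s, p[, 2], xout = stations)$y
  x[c(1, n_out)] <- p[c(1, nrow(p)), 1]
  y[c(1, n_out)] <- p[c(1, nrow(p)), 2]
  out <- cbind(x, y)
  ## merge accidental duplicates (can only arise from repeated input points)
  bt_curve(out)
}
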