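## ODF fields on the unit circle, one density per grid node, stored as
## truncated even-order Fourier coefficients: channels
## (a0, a2, b2, a4, b4, ..., aL, bL) with
##   f(theta) = a0 + sum_k a_{2k} cos(2k theta) + b_{2k} sin(2k theta).
## Odd harmonics are identically zero, so antipodal symmetry
## f(theta) = f(theta + pi) holds by construction; normalization
## int_0^{2pi} f = 2*pi*a0 = 1. The even representation makes directional
## derivatives in theta analytic; spatial gradients of the coefficients are
## cached as central differences on the grid.

odf_orders <- function(L) {
  if (L < 2 || L %% 2 != 0) stop("ODF order L must be an even integer >= 2")
  seq(2, L, by = 2)
}

odf_n_channels <- function(L) 1L + 2L * length(odf_orders(L))

## Fourier coefficients of a sampled density on a uniform theta grid
## (closed, theta_j = 2*pi*(j-1)/N). Returns channel vector.
odf_coeffs_from_samples <- function(fvals, L) {
  n <- length(fvals)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  h <- 2 * pi / n
  a0 <- sum(fvals) * h / (2 * pi)
  co <- c(a0)
  for (m in odf_orders(L)) {
    co <- c(co, sum(fvals * cos(m * theta)) * h / pi,
            sum(fvals * sin(m * theta)) * h / pi)
  }
  co
}

## Evaluate the truncated series (or its theta-derivatives) from a channel
## matrix (n x C) at per-row angles theta.
odf_series_eval <- function(coef, theta, L, deriv = 0L) {
  coef <- matrix(coef, ncol = odf_n_channels(L))
  out <- if (deriv == 0L) coef[, 1] else numeric(nrow(coef))
  j <- 2L
  for (m in odf_orders(L)) {
    a <- coef[, j]; b <- coef[, j + 1L]; j <- j + 2L
    ## d-th derivative of a cos(m t) + b sin(m t)
    ph <- deriv * pi / 2
    out <- out + m^deriv * (a * cos(m * theta + ph) + b * sin(m * theta + ph))
  }
  out
}

#' Gridded orientation-distribution-function (ODF) field
#'
#' Builds an antipodally symmetric ODF field over the unit square from
#' per-node density samples on a uniform angle grid. Each node's density is
#' normalized to integrate to 1, projected on even Fourier harmonics up to
#' order `L`, and repaired if truncation ringing produces negative
#' excursions (clip at zero, renormalize, re-project; any residual negative
#' part is removed by mixing in a small uniform component).
#'
#' @param samples `G1 x G2 x Ntheta` array of non-negative density samples
#'   on `theta_j = 2*pi*(j-1)/Ntheta`, or `NULL` when `coefficients` given.
#' @param L even truncation order (default 8).
#' @param coefficients optional precomputed `G1 x G2 x C` channel array
#'   (channels `a0, a2, b2, ..., aL, bL`); bypasses the sampling path.
#' @return object of class `bt_odf_field`.
#' @export
bt_odf_field <- function(samples = NULL, L = 8L, coefficients = NULL) {
  if (is.null(coefficients)) {
    if (length(dim(samples)) != 3L) stop("samples must be G1 x G2 x Ntheta")
    g1 <- dim(samples)[1]; g2 <- dim(samples)[2]; nt <- dim(samples)[3]
    if (any(samples < 0)) stop("density samples must be non-negative")
    theta <- 2 * pi * (seq_len(nt) - 1) / nt
    co <- array(0, c(g1, g2, odf_n_channels(L)))
    for (i in seq_len(g1)) for (j in seq_len(g2)) {
      f <- samples[i, j, ]
      ## enforce antipodal symmetry, then normalize
      f <- (f + f[1 + (seq_len(nt) - 1 + nt %/% 2) %% nt]) / 2
      s <- sum(f) * 2 * pi / nt
      if (s <= 0) stop("degenerate (zero-mass) ODF sample")
      f <- f / s
      cij <- odf_coeffs_from_samples(f, L)
      fv <- odf_series_eval(matrix(cij, nrow = 1)[rep(1, nt), ], theta, L)
      if (min(fv) < 0) {
        fv <- pmax(fv, 0)
        fv <- fv / (sum(fv) * 2 * pi / nt)
        cij <- odf_coeffs_from_samples(fv, L)
        fv <- odf_series_eval(matrix(cij, nrow = 1)[rep(1, nt), ], theta, L)
        if (min(fv) < 0) {
          ## mix with uniform: (f - m)/(1 - 2*pi*m) with m = min < 0
          m <- min(fv)
          cij <- cij / (1 - 2 * pi * m)
          cij[1] <- (cij[1] * (1 - 2 * pi * m) - m) / (1 - 2 * pi * m)
        }
      }
      co[i, j, ] <- cij
    }
  } else {
    co <- coefficients
    if (length(dim(co)) != 3L || dim(co)[3] != odf_n_channels(L))
      stop("coefficients must be G1 x G2 x (1 + L) channels for order L")
    g1 <- dim(co)[1]; g2 <- dim(co)[2]
    if (any(abs(co[, , 1] - 1 / (2 * pi)) > 1e-6))
      stop("a0 channel must equal 1/(2*pi): ODFs integrate to 1")
  }
  grad <- lapply(seq_len(dim(co)[3]), function(k)
    grid_gradient(matrix(co[, , k], g1, g2), g1, g2))
  structure(list(g1 = g1, g2 = g2, L = as.integer(L), coef = co,
                 grad = grad), class = "bt_odf_field")
}

#' @export
print.bt_odf_field <- function(x, ...) {
  cat(sprintf("<bt_odf_field: %d x %d grid, Fourier order L = %d>\n",
              x$g1, x$g2, x$L))
  invisible(x)
}

## Vectorized evaluation machinery: interpolate channels (and, optionally,
## their spatial gradients) at query points, then evaluate the series.
odf_channels_at <- function(field, xy, spatial = c("none", "dx", "dy")) {
  spatial <- match.arg(spatial)
  w <- bilinear_nodes(field, xy)
  C <- dim(field$coef)[3]
  out <- matrix(0, nrow(matrix(xy, ncol = 2)), C)
  for (k in seq_len(C)) {
    z <- if (spatial == "none") matrix(field$coef[, , k], field$g1, field$g2)
         else if (spatial == "dx") field$grad[[k]]$dx else field$grad[[k]]$dy
    out[, k] <- interp_channel(z, w, field$g1)
  }
  out
}

## Interpolant-exact spatial derivatives of all coefficient channels at
## query points: list(dx = n x C, dy = n x C). Used by the analytic ODF
## energy gradient (self-consistent with the energy's interpolation).
odf_channels_grad_at <- function(field, xy) {
  w <- bilinear_nodes(field, xy)
  C <- dim(field$coef)[3]
  n <- nrow(matrix(xy, ncol = 2))
  dx <- matrix(0, n, C); dy <- matrix(0, n, C)
  for (k in seq_len(C)) {
    g <- interp_channel_grad(matrix(field$coef[, , k], field$g1, field$g2),
                             w, field$g1, field$g2)
    dx[, k] <- g$dx; dy[, k] <- g$dy
  }
  list(dx = dx, dy = dy)
}

#' Evaluate an ODF (and derivatives) at a point and direction
#'
#' Bilinearly interpolates the Fourier coefficients at `x` and evaluates the
#' series at the angle of `direction`. `deriv` selects the analytic
#' derivative order with respect to the angle; `spatial` selects the
#' spatial partial derivative of the field (from cached central differences
#' of the coefficients).
#'
#' @param field a [bt_odf_field()].
#' @param x length-2 domain point.
#' @param direction length-2 unit vector.
#' @param deriv angle-derivative order 0, 1 or 2.
#' @param spatial `"none"`, `"dx"` or `"dy"`.
#' @return scalar density (or derivative) value.
#' @export
evaluate_odf <- function(field, x, direction, deriv = 0L,
                         spatial = c("none", "dx", "dy")) {
  nd <- sqrt(sum(direction^2))
  if (abs(nd - 1) > 1e-6) stop("direction must be a unit vector")
  theta <- atan2(direction[2], direction[1])
  co <- odf_channels_at(field, matrix(x, ncol = 2), match.arg(spatial))
  odf_series_eval(co, theta, field$L, deriv = as.integer(deriv))
}
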