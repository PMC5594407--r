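## The three energy terms of the posterior
##   E_total = lambda1 E_data + lambda2 E_prior + lambda3 E_smooth
## and their L2 gradients along the curve. All energies are pure functions
## of (field, curve); gradients are full-length T x 2 fields — masking the
## endpoint entries is the tracker's job.

## Exact adjoint of the discretized first variation. The discrete energy is
## sum_j w_j g(beta_j, v_j) with trapezoid weights w and stencil velocities
## v; given the pointwise partials gbeta = dg/dbeta and gv = dg/dv, this
## assembles dE/dbeta_i / w_i, i.e. the L2 gradient of the functional as
## actually discretized (the continuum limit is the usual
## dg/dbeta - d/dt dg/dv of the lemma-form gradients).
adjoint_gradient <- function(gbeta, gv, n) {
  h <- 1 / (n - 1)
  w <- rep(h, n); w[c(1, n)] <- h / 2
  adj <- gbeta * w
  i <- 3:n          # contribution of interior v_j to the point j + 1
  adj[i, ] <- adj[i, ] + (w[i - 1] * gv[i - 1, , drop = FALSE]) / (2 * h)
  i <- 1:(n - 2)    # contribution of interior v_j to the point j - 1
  adj[i, ] <- adj[i, ] - (w[i + 1] * gv[i + 1, , drop = FALSE]) / (2 * h)
  ## one-sided endpoint stencils: v_1 = (-3b1 + 4b2 - b3)/(2h), v_n mirror
  adj[1, ] <- adj[1, ] - 3 * w[1] * gv[1, ] / (2 * h)
  adj[2, ] <- adj[2, ] + 4 * w[1] * gv[1, ] / (2 * h)
  adj[3, ] <- adj[3, ] - w[1] * gv[1, ] / (2 * h)
  adj[n, ] <- adj[n, ] + 3 * w[n] * gv[n, ] / (2 * h)
  adj[n - 1, ] <- adj[n - 1, ] - 4 * w[n] * gv[n, ] / (2 * h)
  adj[n - 2, ] <- adj[n - 2, ] + w[n] * gv[n, ] / (2 * h)
  adj / w
}

## Apply symmetric 2x2 tensors (channel vectors xx, xy, yy) to row vectors.
sym_apply <- function(ch, V) {
  cbind(ch$xx * V[, 1] + ch$xy * V[, 2],
        ch$xy * V[, 1] + ch$yy * V[, 2])
}

## Quadratic form n' S n rowwise.
sym_quad <- function(ch, N) {
  ch$xx * N[, 1]^2 + 2 * ch$xy * N[, 1] * N[, 2] + ch$yy * N[, 2]^2
}

#' Tensor-field data energy of a curve
#'
#' Trapezoidal quadrature of `n(t)' M^-1(beta(t)) n(t)` over the uniform
#' parameter, where `n` is the unit tangent. The integrand depends on the
#' tangent direction only, so the energy is invariant to a constant
#' rescaling of traversal speed. Setting `reparam_invariant = TRUE` changes
#' the integration measure from `dt` to `|betadot(t)| dt`, which makes the
#' value invariant to any reparameterization (at the price of weighting by
#' local speed).
#'
#' @param field a [bt_tensor_field()].
#' @param curve a [bt_curve()].
#' @param reparam_invariant logical, default `FALSE`.
#' @return scalar energy.
#' @export
e_data_tensor <- function(field, curve, reparam_invariant = FALSE) {
  d <- curve_derivatives(curve)
  B <- interp_tensor_channels(field, unclass(curve), "Minv")
  integrand <- sym_quad(B, d$tangent)
  t <- seq(0, 1, length.out = nrow(curve))
  if (reparam_invariant) integrand <- integrand * d$speed
  trapz(t, integrand)
}

#' Analytic gradient of the tensor data energy
#'
#' First variation of [e_data_tensor()] under the L2 inner product on
#' `[0, 1]`: the spatial term has `i`-th component `n' (dM^-1/dx_i) n`
#' (evaluated with the exact derivative of the interpolated inverse field),
#' and the momentum term `(2/|betadot|) (M^-1 n - (n' M^-1 n) n)` enters
#' through the outer time derivative, which is applied as the exact
#' discrete adjoint of the stencil/trapezoid scheme so the returned field
#' is the gradient of the energy exactly as discretized. Endpoint rows use
#' one-sided stencils; the tracker masks them.
#'
#' @inheritParams e_data_tensor
#' @return T x 2 gradient field.
#' @export
grad_e_data_tensor <- function(field, curve) {
  d <- curve_derivatives(curve)
  p <- unclass(curve)
  n <- d$tangent; sp <- d$speed
  B <- interp_tensor_channels(field, p, "Minv")
  G <- interp_gradient_exact(field, p, "Minv")
  Bn <- sym_apply(B, n)
  nBn <- sym_quad(B, n)
  ## dg/dbeta: i-th component n' (dM^-1/dx_i) n
  gbeta <- cbind(sym_quad(list(xx = G$xx$dx, xy = G$xy$dx, yy = G$yy$dx), n),
                 sym_quad(list(xx = G$xx$dy, xy = G$xy$dy, yy = G$yy$dy), n))
  ## dg/dv: (2/|v|) (M^-1 n - (n' M^-1 n) n)
  gv <- (2 / sp) * (Bn - nBn * n)
  adjoint_gradient(gbeta, gv, nrow(p))
}

#' Length (smoothness) energy of a curve
#'
#' The polyline length, a discretization of `int |betadot| dt`; invariant to
#' reparameterization of the same geometry.
#'
#' @param curve a [bt_curve()].
#' @return scalar length.
#' @export
e_smooth <- function(curve) curve_length(curve)

#' Analytic gradient of the length energy
#'
#' The L2 gradient of curve length with fixed endpoints is
#' `-d/dt (unit tangent)`, the curvature-flow field scaled by local speed
#' and pointing away from the osculating center (so that a gradient-descent
#' step shrinks and smooths the curve, as in Euclidean heat flow). The
#' derivative is assembled as the exact adjoint of the polyline-length
#' discretization: `(u_{i-1} - u_i) / w_i` with `u_s` the unit segment
#' directions and `w` the trapezoid weights.
#'
#' @param curve a [bt_curve()].
#' @return T x 2 gradient field.
#' @export
grad_e_smooth <- function(curve) {
  p <- unclass(bt_curve(curve))
  n <- nrow(p)
  seg <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
  u <- seg / sqrt(rowSums(seg^2))
  h <- 1 / (n - 1)
  w <- rep(h, n); w[c(1, n)] <- h / 2
  G <- rbind(-u[1, , drop = FALSE],
             u[-(n - 1), , drop = FALSE] - u[-1, , drop = FALSE],
             u[n - 1, , drop = FALSE])
  G / w
}

#' ODF-field data energy of a curve
#'
#' Trapezoidal quadrature of `-f_beta(t)(n(t))`: low where the tangent is
#' aligned with the local ODF peaks.
#'
#' @param field a [bt_odf_field()].
#' @param curve a [bt_curve()].
#' @return scalar energy (negative of mean density along the curve).
#' @export
e_data_odf <- function(field, curve) {
  d <- curve_derivatives(curve)
  theta <- atan2(d$tangent[, 2], d$tangent[, 1])
  co <- odf_channels_at(field, unclass(curve), "none")
  f <- odf_series_eval(co, theta, field$L)
  t <- seq(0, 1, length.out = nrow(curve))
  trapz(t, -f)
}

#' Analytic gradient of the ODF data energy
#'
#' First variation of [e_data_odf()] under the L2 inner product: the
#' spatial term is `-grad_x f` at the current tangent angle (exact
#' derivative of the interpolated Fourier coefficients), and the angular
#' momentum term `-(1/|betadot|) df/dtheta e_theta` (with `e_theta` the
#' 90-degree rotation of the tangent, from the analytic angle derivative of
#' the Fourier series) enters through the outer time derivative, applied as
#' the exact discrete adjoint of the stencil/trapezoid scheme.
#'
#' @inheritParams e_data_odf
#' @return T x 2 gradient field.
#' @export
grad_e_data_odf <- function(field, curve) {
  d <- curve_derivatives(curve)
  p <- unclass(curve)
  n <- d$tangent; sp <- d$speed
  etheta <- rot90_ccw(n)
  theta <- atan2(n[, 2], n[, 1])
  co <- odf_channels_at(field, p, "none")
  cg <- odf_channels_grad_at(field, p)
  L <- field$L
  f1 <- odf_series_eval(co, theta, L, 1L)
  ## dg/dbeta = -grad_x f ; dg/dv = -f_theta e_theta / |v|
  gbeta <- -cbind(odf_series_eval(cg$dx, theta, L, 0L),
                  odf_series_eval(cg$dy, theta, L, 0L))
  gv <- -(f1 / sp) * etheta
  adjoint_gradient(gbeta, gv, nrow(p))
}

#' Evaluate all active energy terms of a tracker configuration
#'
#' @param curve a [bt_curve()].
#' @param field tensor or ODF field (matching `cfg$data_mode`).
#' @param model a [bt_shape_model()] or `NULL`.
#' @param cfg a [tracker_config()].
#' @param prior_state optional frozen alignment state for the prior term
#'   (see [prior_align_state()]).
#' @return named list `e_data`, `e_prior`, `e_smooth`, `e_total`.
#' @export
energy_terms <- function(curve, field, model, cfg, prior_state = NULL) {
  ed <- if (cfg$lambda1 > 0) {
    if (cfg$data_mode == "tensor") e_data_tensor(field, curve)
    else e_data_odf(field, curve)
  } else 0
  ep <- if (cfg$lambda2 > 0)
    e_prior_curve(curve, model, state = prior_state) else 0
  es <- if (cfg$lambda3 > 0) e_smooth(curve) else 0
  list(e_data = ed, e_prior = ep, e_smooth = es,
       e_total = cfg$lambda1 * ed + cfg$lambda2 * ep + cfg$lambda3 * es)
}
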