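## Elastic shape analysis of open planar curves in the square-root velocity
## (SRVF) representation. A unit-length curve maps to q = betadot/sqrt(|betadot|)
## with int |q|^2 dt = length = 1, so shapes live on the unit sphere of
## L2([0,1], R^2) modulo rotations SO(2) and reparameterizations Gamma. All
## inner products below are the L2 inner product with trapezoid weights on
## the uniform parameter grid.

## trapezoid weight vector on a T-point uniform grid (sums to 1)
trapz_weights <- function(n) {
  w <- rep(1 / (n - 1), n)
  w[c(1, n)] <- w[c(1, n)] / 2
  w
}

#' L2 inner product of two T x 2 function samples
#' @param u,v T x 2 matrices on the uniform parameter grid.
#' @return scalar `int u(t).v(t) dt` (trapezoid rule).
#' @export
q_inner <- function(u, v) sum(trapz_weights(nrow(u)) * rowSums(u * v))

q_norm <- function(u) sqrt(max(q_inner(u, u), 0))

q_normalize <- function(u) u / q_norm(u)

#' Square-root velocity transform of a curve
#'
#' The curve is first rescaled to unit length (the shape model is
#' scale-free), then `q(t) = betadot(t)/sqrt(|betadot(t)|)` is computed with
#' the stencil derivatives and projected exactly onto the unit preshape
#' sphere (`int |q|^2 dt = 1`).
#'
#' @param curve a [bt_curve()] or plain T x 2 matrix.
#' @return T x 2 matrix of class `bt_srvf`.
#' @export
curve_to_srvf <- function(curve) {
  p <- as.matrix(unclass(curve))
  L <- sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
  if (L <= 0) stop("degenerate curve: zero length")
  v <- stencil_deriv(p / L)
  sp <- sqrt(rowSums(v^2))
  if (any(sp <= 0)) stop("degenerate curve: zero velocity sample")
  q <- v / sqrt(sp)
  q <- q_normalize(q)
  class(q) <- c("bt_srvf", "matrix", "array")
  q
}

#' Inverse square-root velocity transform
#'
#' Integrates `q |q|` (cumulative trapezoid), producing the unit-length
#' curve starting at the origin, then applies `origin + scale * beta`.
#'
#' @param q T x 2 SRVF matrix.
#' @param origin length-2 translation (default `c(0, 0)`).
#' @param scale positive scale (default 1).
#' @return T x 2 coordinate matrix (not domain-validated).
#' @export
srvf_to_curve <- function(q, origin = c(0, 0), scale = 1) {
  q <- as.matrix(unclass(q))
  n <- nrow(q)
  v <- q * sqrt(rowSums(q^2))
  h <- 1 / (n - 1)
  cum <- apply(v, 2, function(col) c(0, cumsum((col[-1] + col[-n]) / 2 * h)))
  sweep(cum * scale, 2, origin, `+`)
}

## Apply a reparameterization gamma (values on the uniform grid) to an SRVF:
## (q o gamma) sqrt(gammadot), gammadot from stencil differentiation of gamma.
apply_gamma_srvf <- function(q, gamma) {
  n <- nrow(q)
  t <- seq(0, 1, length.out = n)
  gd <- as.vector(stencil_deriv(matrix(gamma, ncol = 1)))
  gd <- pmax(gd, 1e-8)
  qx <- approx(t, q[, 1], xout = clamp(gamma, 0, 1))$y
  qy <- approx(t, q[, 2], xout = clamp(gamma, 0, 1))$y
  cbind(qx, qy) * sqrt(gd)
}

invert_gamma <- function(gamma) {
  n <- length(gamma)
  t <- seq(0, 1, length.out = n)
  g <- cummax(gamma)          # guard monotonicity against rounding
  approx(g, t, xout = t, rule = 2, ties = "ordered")$y
}

## Continuous refinement of a DP reparameterization: projected gradient
## descent on the gamma values themselves (compiled kernel), using the
## analytic functional gradient of the misfit
## J(gamma) = int |q1 - (q2 o gamma) sqrt(gammadot)|^2 with endpoints fixed
## and monotonicity enforced by step rejection. Polishes away the slope
## quantization of the lattice DP.
refine_gamma <- function(q1, q2, gamma0, max_iter = 300L, step0 = 0.1) {
  as.numeric(.refine_gamma_cpp(q1, q2, gamma0, as.integer(max_iter), step0))
}

## Optimal rotation (Procrustes, weighted cross-covariance + SVD).
optimal_rotation <- function(q1, q2) {
  w <- trapz_weights(nrow(q1))
  A <- t(q1 * w) %*% q2
  sv <- svd(A)
  O <- sv$u %*% diag(c(1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  O
}

#' Align one SRVF to another over rotation and reparameterization
#'
#' Alternates Procrustes rotation (SVD of the 2x2 cross-covariance) and
#' reparameterization until the preshape distance stops improving (at most
#' `max_alt` alternations). The reparameterization step is dynamic
#' programming on the T x T lattice followed by a continuous
#' gradient-descent polish (`method = "dp"`), the polish alone started from
#' the identity (`method = "refine"`, much faster, adequate for mild
#' warps), or the fast path with automatic fallback to DP when it leaves a
#' substantial residual (`method = "auto"`).
#'
#' @param q1 reference SRVF (T x 2, unit norm).
#' @param q2 SRVF to align.
#' @param max_alt maximum rotation/reparameterization alternations.
#' @param dp_step largest lattice slope numerator/denominator for the DP.
#' @param method `"dp"`, `"refine"` or `"auto"` (see above).
#' @param symmetric also run the DP in the reverse direction and keep the
#'   better realized warp (the lattice slope cap binds asymmetrically).
#' @return list with `rotation` (2x2), `gamma` (length T), `q2_aligned`
#'   (unit-norm T x 2) and `distance` (great-circle arc length on the
#'   preshape sphere).
#' @export
align_shapes <- function(q1, q2, max_alt = 10L, dp_step = 4L,
                         method = c("dp", "refine", "auto"),
                         symmetric = FALSE) {
  method <- match.arg(method)
  q1 <- q_normalize(as.matrix(unclass(q1)))
  q2 <- as.matrix(unclass(q2))
  O_tot <- diag(2)
  n <- nrow(q1)
  t_grid <- seq(0, 1, length.out = n)
  gamma_tot <- t_grid
  q2c <- q_normalize(q2)
  best <- acos(clamp(q_inner(q1, q2c), -1, 1))
  d0 <- best
  for (it in seq_len(max_alt)) {
    O <- optimal_rotation(q1, q2c)
    q2r <- q2c %*% t(O)
    cand <- list()
    if (method %in% c("refine", "auto"))
      cand <- c(cand, list(refine_gamma(q1, q2r, t_grid)))
    need_dp <- method == "dp"
    if (method == "auto" && it == 1L) {
      ## in auto mode run the DP only if the fast path left a residual
      fast_d <- {
        qg <- q_normalize(apply_gamma_srvf(q2r, cand[[1]]))
        acos(clamp(q_inner(q1, qg), -1, 1))
      }
      need_dp <- fast_d > 0.1 && fast_d > 0.5 * d0
    }
    if (need_dp) {
      dp_f <- .dp_align_cpp(q1, q2r, as.integer(dp_step))
      cand <- c(cand, list(refine_gamma(q1, q2r, dp_f$gamma)))
      if (symmetric) {
        dp_b <- .dp_align_cpp(q2r, q1, as.integer(dp_step))
        cand <- c(cand, list(refine_gamma(q1, q2r,
                                          invert_gamma(dp_b$gamma))))
      }
    }
    best_c <- NULL; best_d <- Inf
    for (gam_c in cand) {
      qg <- q_normalize(apply_gamma_srvf(q2r, gam_c))
      dc <- acos(clamp(q_inner(q1, qg), -1, 1))
      if (dc < best_d) { best_d <- dc; best_c <- list(gam = gam_c, q = qg) }
    }
    improved <- best_d < best - 1e-10
    if (best_d < best) {
      best <- best_d
      O_tot <- O %*% O_tot
      ## gamma_total(t) = gamma_old(gamma_new(t))
      gamma_tot <- approx(t_grid, gamma_tot, xout = best_c$gam, rule = 2)$y
      q2c <- best_c$q
    }
    if (!improved) break
  }
  list(rotation = O_tot, gamma = gamma_tot, q2_aligned = q2c, distance = best)
}

#' Geodesic distance between two shapes
#' @param q1,q2 SRVFs (or curves, converted automatically).
#' @param ... passed to [align_shapes()].
#' @return great-circle distance after alignment.
#' @export
shape_distance <- function(q1, q2, ...) {
  if (!inherits(q1, "bt_srvf")) q1 <- curve_to_srvf(q1)
  if (!inherits(q2, "bt_srvf")) q2 <- curve_to_srvf(q2)
  align_shapes(q1, q2, ...)$distance
}

#' Sphere exponential map, inverse, and parallel transport
#'
#' Great-circle geometry of the unit preshape sphere in
#' `L2([0,1], R^2)`: `exp_map(mu, v)` shoots from `mu` along tangent `v`;
#' `inv_exp_map(mu, q)` returns the shooting vector (aligning `q` to `mu`
#' first when `align = TRUE`); `parallel_transport(w, mu, q)` carries a
#' tangent vector at `mu` to `q` along the connecting great circle.
#'
#' @param mu unit-norm T x 2 base point.
#' @param v tangent vector at `mu` (`q_inner(v, mu) = 0`), with
#'   `q_norm(v) < pi` (the injectivity radius, matching the truncation of
#'   the wrapped-normal prior).
#' @return `exp_map`: unit-norm T x 2 point.
#' @export
exp_map <- function(mu, v) {
  nv <- q_norm(v)
  if (nv >= pi) stop("tangent norm >= pi: outside the truncation region")
  if (nv < 1e-12) return(mu)
  q_normalize(cos(nv) * mu + sin(nv) * (v / nv))
}

#' @rdname exp_map
#' @param q unit-norm T x 2 point to lift.
#' @param align align `q` to `mu` over rotation/reparameterization first.
#' @param method alignment method passed to [align_shapes()].
#' @export
inv_exp_map <- function(mu, q, align = TRUE, method = "auto") {
  if (align) q <- align_shapes(mu, q, method = method)$q2_aligned
  ip <- clamp(q_inner(mu, q), -1, 1)
  theta <- acos(ip)
  if (theta >= pi) stop("antipodal shapes: outside the truncation region")
  if (theta < 1e-12) return(q * 0)
  u <- q - ip * mu
  theta * u / q_norm(u)
}

#' @rdname exp_map
#' @param w tangent vector at `mu` to transport.
#' @export
parallel_transport <- function(w, mu, q) {
  ip <- clamp(q_inner(mu, q), -1, 1)
  if (ip <= -1 + 1e-12) stop("antipodal shapes: transport undefined")
  w - (q_inner(w, q) / (1 + ip)) * (mu + q)
}

#' Karcher (Frechet) mean of a set of shapes
#'
#' Standard fixed-point iteration: align every shape to the current mean,
#' average the shooting vectors, and step along the exponential map with
#' step size 0.5, until the mean shooting-vector norm drops below `tol`.
#'
#' @param shapes list of SRVFs (or curves).
#' @param tol convergence tolerance on the mean shooting-vector norm.
#' @param max_iter maximum iterations; non-convergence warns and returns the
#'   best iterate.
#' @param align_method alignment method passed to [align_shapes()]
#'   (default `"auto"`; the data are concentrated around the evolving mean).
#' @return unit-norm T x 2 SRVF of class `bt_srvf`.
#' @export
karcher_mean <- function(shapes, tol = 1e-3, max_iter = 25L,
                         align_method = "auto") {
  if (length(shapes) < 2L) stop("need at least 2 shapes")
  qs <- lapply(shapes, function(s)
    if (inherits(s, "bt_srvf")) unclass(s) else unclass(curve_to_srvf(s)))
  mu <- q_normalize(Reduce(`+`, qs) / length(qs))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    vs <- lapply(qs, function(q) inv_exp_map(mu, q, method = align_method))
    vbar <- Reduce(`+`, vs) / length(vs)
    if (q_norm(vbar) < tol) { converged <- TRUE; break }
    mu <- exp_map(mu, 0.5 * vbar)
  }
  if (!converged) warning("Karcher mean did not converge in ", max_iter,
                          " iterations; returning best iterate")
  class(mu) <- c("bt_srvf", "matrix", "array")
  mu
}
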