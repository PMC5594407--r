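## Statistical shape model: tangent-space PCA at the Karcher mean and the
## truncated wrapped-normal prior energy
##   E_prior(q) = 1/2 v' (Um Sm^-1 Um') v + 1/(2 delta^2) |v - Um Um' v|^2,
## with v = inv_exp_map(mu, [q]), Um the top-m principal directions, Sm the
## principal variances, and delta the tail scale (< min Sm). The normalizing
## constant of the density never enters the energy and is not computed.

flatten_w <- function(v, sqw) as.vector(v * sqw)
unflatten_w <- function(z, sqw) matrix(z, ncol = 2) / sqw

#' Tangent principal component analysis at a Karcher mean
#'
#' Shooting vectors `v_i = inv_exp_map(mean, shape_i)` are computed in the
#' tangent space at the mean, their covariance is diagonalized (SVD in
#' L2-weighted coordinates, so the basis is L2-orthonormal), and the top `m`
#' directions with their variances parameterize the prior. The tail scale is
#' set to `delta_factor` times the smallest retained variance.
#'
#' @param shapes list of SRVFs or curves (training fibers).
#' @param mean Karcher mean SRVF (computed with [karcher_mean()] if `NULL`).
#' @param m retained dimension; `NULL` selects the smallest `m` explaining
#'   `var_explained` of total variance, capped at `m_max` and `n - 1`.
#' @param var_explained variance fraction for automatic `m` (default 0.95).
#' @param m_max cap on the retained dimension (default 5).
#' @param delta_factor tail standard deviation as a fraction of the
#'   smallest retained mode's standard deviation (default 0.5, so the tail
#'   variance `delta^2` is a quarter of the smallest retained variance —
#'   the tail is tighter than every retained mode).
#' @return object of class `bt_shape_model`: list with `mean` (T x 2 SRVF),
#'   `U` (T x 2 x m L2-orthonormal basis), `S` (length-m variances,
#'   nonincreasing), `delta`, `m`, `n_train`, `all_S`.
#' @export
tangent_pca <- function(shapes, mean = NULL, m = NULL, var_explained = 0.95,
                        m_max = 5L, delta_factor = 0.5) {
  qs <- lapply(shapes, function(s)
    if (inherits(s, "bt_srvf")) unclass(s) else unclass(curve_to_srvf(s)))
  n <- length(qs)
  if (n < 2L) stop("need at least 2 training shapes")
  if (is.null(mean)) mean <- karcher_mean(shapes)
  mu <- unclass(mean)
  nT <- nrow(mu)
  sqw <- sqrt(trapz_weights(nT))
  vs <- lapply(qs, function(q) inv_exp_map(mu, q, method = "auto"))
  Z <- do.call(rbind, lapply(vs, flatten_w, sqw = sqw))  # n x 2T
  Z <- sweep(Z, 2, colMeans(Z))   # center in the tangent space
  sv <- svd(Z / sqrt(n), nu = 0)
  vars <- sv$d^2                  # principal variances of the covariance K
  pos <- vars > max(vars) * 1e-12
  vars <- vars[pos]
  V <- sv$v[, pos, drop = FALSE]
  if (is.null(m)) {
    cum <- cumsum(vars) / sum(vars)
    m <- min(which(cum >= var_explained), m_max, n - 1L)
  }
  m <- as.integer(m)
  if (m > length(vars))
    stop("m = ", m, " exceeds the available tangent dimension ", length(vars))
  U <- array(0, c(nT, 2, m))
  for (j in seq_len(m)) {
    u <- unflatten_w(V[, j], sqw)
    u <- u - q_inner(u, mu) * mu      # enforce tangency numerically
    U[, , j] <- u / q_norm(u)
  }
  S <- vars[seq_len(m)]
  structure(list(mean = mean, U = U, S = S,
                 delta = delta_factor * sqrt(min(S)), m = m,
                 n_train = n, all_S = vars),
            class = "bt_shape_model")
}

#' @export
print.bt_shape_model <- function(x, ...) {
  cat(sprintf("<bt_shape_model: T = %d, m = %d, delta = %.4g, n_train = %d>\n",
              nrow(x$mean), x$m, x$delta, x$n_train))
  cat("  principal variances:", signif(x$S, 4), "\n")
  invisible(x)
}

## Project a tangent vector on the model basis; returns coefficients and the
## orthogonal residual.
model_split <- function(model, v) {
  cf <- vapply(seq_len(model$m), function(j) q_inner(v, model$U[, , j]),
               numeric(1))
  vpar <- Reduce(`+`, lapply(seq_len(model$m),
                             function(j) cf[j] * model$U[, , j]))
  list(coef = cf, vpar = vpar, vperp = v - vpar)
}

#' Shape-prior energy of an SRVF
#'
#' The negative log-density exponent of the truncated wrapped-normal shape
#' model (up to its normalizing constant): zero exactly when the shape of
#' `q` equals the model mean's shape.
#'
#' @param q SRVF (T x 2); aligned to the model mean internally.
#' @param model a [tangent_pca()] model.
#' @param align align `q` to the mean over rotation/reparameterization
#'   first (default `TRUE`; the prior lives on shape orbits). With
#'   `align = FALSE` the energy is the raw quadratic form in the given
#'   preshape coordinates.
#' @return scalar energy, `>= 0`.
#' @export
e_prior <- function(q, model, align = TRUE) {
  v <- inv_exp_map(unclass(model$mean), q_normalize(as.matrix(unclass(q))),
                   align = align, method = "auto")
  sp <- model_split(model, v)
  0.5 * sum(sp$coef^2 / model$S) + 0.5 * q_inner(sp$vperp, sp$vperp) / model$delta^2
}

#' @rdname e_prior
#' @param curve a [bt_curve()] (rescaled to unit length internally).
#' @param state optional frozen alignment state from [prior_align_state()]:
#'   the rotation/reparameterization are held fixed instead of re-optimized,
#'   making the energy a smooth function of the curve (an upper bound on
#'   the orbit-aligned energy, tight at the curve the state was computed
#'   at). Used by the tracker, which re-aligns only periodically.
#' @export
e_prior_curve <- function(curve, model, state = NULL) {
  if (is.null(state)) return(e_prior(curve_to_srvf(curve), model))
  q_al <- apply_prior_state(curve_to_srvf(curve), state)
  v <- inv_exp_map(unclass(model$mean), q_al, align = FALSE)
  sp <- model_split(model, v)
  0.5 * sum(sp$coef^2 / model$S) +
    0.5 * q_inner(sp$vperp, sp$vperp) / model$delta^2
}

#' Frozen alignment state for tracker iterations
#'
#' Aligns the curve's shape to the model mean once and returns the
#' rotation and reparameterization as a reusable state, so subsequent
#' prior evaluations are smooth in the curve.
#'
#' @param curve a [bt_curve()].
#' @param model a [tangent_pca()] model.
#' @return list with `rotation` (2x2) and `gamma` (length T).
#' @export
prior_align_state <- function(curve, model) {
  mu <- unclass(model$mean)
  q <- unclass(curve_to_srvf(curve))
  al <- align_shapes(mu, q, method = "auto")
  ## the alternated alignment composes its warps by repeated interpolation;
  ## polish the composed (rotation, gamma) so that their one-shot
  ## application — which is how the frozen state is evaluated — is itself
  ## optimal
  O <- al$rotation
  gam <- al$gamma
  for (k in 1:2) {
    qr <- q %*% t(O)
    gam <- refine_gamma(mu, qr, gam)
    qg <- q_normalize(apply_gamma_srvf(qr, gam))
    O2 <- optimal_rotation(mu, qg)
    O <- O2 %*% O
  }
  list(rotation = O, gamma = gam)
}

## apply a frozen (rotation, gamma) state to an SRVF
apply_prior_state <- function(q, state) {
  q_normalize(apply_gamma_srvf(as.matrix(unclass(q)) %*% t(state$rotation),
                               state$gamma))
}

#' Shape-prior gradient on the preshape sphere
#'
#' Computes `w = A v` with `A = Um Sm^-1 Um' + (I - Um Um')/delta^2` in the
#' tangent space at the mean and parallel-transports it to the aligned
#' `q` — the analytic part of the prior gradient.
#'
#' @inheritParams e_prior
#' @param state optional frozen alignment state (see [prior_align_state()]).
#' @return list with `w_bar` (transported gradient, tangent at `q_aligned`),
#'   `q_aligned`, `rotation`, `gamma`, `v`.
#' @export
grad_e_prior_q <- function(q, model, state = NULL) {
  mu <- unclass(model$mean)
  if (is.null(state)) {
    al <- align_shapes(mu, q_normalize(as.matrix(unclass(q))),
                       method = "auto")
  } else {
    al <- list(q2_aligned = apply_prior_state(q, state),
               rotation = state$rotation, gamma = state$gamma)
  }
  v <- inv_exp_map(mu, al$q2_aligned, align = FALSE)
  if (q_norm(v) >= pi) stop("shooting vector norm >= pi: outside truncation region")
  sp <- model_split(model, v)
  w <- Reduce(`+`, lapply(seq_len(model$m), function(j)
    (sp$coef[j] / model$S[j]) * model$U[, , j])) + sp$vperp / model$delta^2
  w_bar <- parallel_transport(w, mu, al$q2_aligned)
  list(w_bar = w_bar, q_aligned = al$q2_aligned, rotation = al$rotation,
       gamma = al$gamma, v = v)
}

## Reconstruct a domain-frame curve from an SRVF in the mean-aligned frame:
## undo rotation and reparameterization, integrate, and rigidly register to
## the reference normalized curve (rotation + translation from `reg`), then
## pin the endpoints by a linear ramp.
prior_reconstruct <- function(q_al, rotation, gamma, reg) {
  q <- q_al %*% rotation            # q_al = O q  =>  q = O' q_al ; O' = t(O)
  gi <- invert_gamma(gamma)
  q <- apply_gamma_srvf(q, gi)
  b <- srvf_to_curve(q_normalize(q))
  b <- sweep(b, 2, colMeans(b)) %*% t(reg$R)
  b <- sweep(b, 2, reg$center, `+`)
  n <- nrow(b)
  tt <- seq(0, 1, length.out = n)
  b + outer(1 - tt, reg$a - b[1, ]) + outer(tt, reg$b - b[n, ])
}

#' Shape-prior gradient in curve space
#'
#' Converts the transported prior gradient `w_bar` to a displacement field
#' on the curve points by a finite-difference construction: step the aligned
#' SRVF by `-fd_step * w_bar`, map back through the inverse of the
#' alignment, reconstruct the curve preserving the original endpoints,
#' length and orientation (rigid re-registration plus endpoint pinning —
#' placement, scale and rotation are nuisance variables controlled by the
#' data term only), and divide the displacement by `fd_step`. The zero-step
#' reconstruction through the identical chain is used as the reference so
#' that alignment round-trip error cancels and the gradient vanishes
#' exactly at the mean shape.
#'
#' @param curve a [bt_curve()].
#' @param model a [tangent_pca()] model.
#' @param fd_step finite-difference step on the preshape sphere
#'   (default 1e-3).
#' @param state optional frozen alignment state (see [prior_align_state()]).
#' @return T x 2 gradient field in domain units.
#' @export
grad_e_prior_curve <- function(curve, model, fd_step = 1e-3, state = NULL) {
  p <- as.matrix(unclass(curve))
  L <- curve_length(bt_curve(p, validate = FALSE))
  pn <- p / L
  q <- curve_to_srvf(p)
  g <- grad_e_prior_q(q, model, state = state)
  ## adaptive step: keep the sphere move small when the gradient is large,
  ## so the finite-difference conversion stays in its linear regime
  fd_step <- fd_step / max(1, q_norm(g$w_bar))
  ## registration target computed once, from the zero-step reconstruction
  b0_raw <- {
    qq <- g$q_aligned %*% g$rotation
    qq <- apply_gamma_srvf(qq, invert_gamma(g$gamma))
    srvf_to_curve(q_normalize(qq))
  }
  ctr <- colMeans(pn)
  R <- optimal_rotation(sweep(pn, 2, ctr), sweep(b0_raw, 2, colMeans(b0_raw)))
  reg <- list(R = R, center = ctr, a = pn[1, ], b = pn[nrow(pn), ])
  b0 <- prior_reconstruct(g$q_aligned, g$rotation, g$gamma, reg)
  q1 <- q_normalize(g$q_aligned - fd_step * g$w_bar)
  b1 <- prior_reconstruct(q1, g$rotation, g$gamma, reg)
  L * (b0 - b1) / fd_step
}


## Exact gradient of the frozen-alignment prior energy with respect to the
## curve points: reverse-mode chain rule through
##   p -> p/L -> stencil velocity -> q = v/sqrt(|v|) -> normalize ->
##   rotate (frozen O) -> warp (frozen gamma) -> normalize ->
##   inverse exponential map at mu -> quadratic form.
## Returned in the same per-point-partial / trapezoid-weight convention as
## the other energy gradients. Used by the tracker: the finite-difference
## q-step conversion of grad_e_prior_curve is adequate for descent in
## gentle regions but is not accurate enough for backtracking on the stiff
## tail modes of the prior.
prior_grad_frozen <- function(curve, model, state) {
  p <- as.matrix(unclass(curve))
  nT <- nrow(p)
  w <- trapz_weights(nT)
  mu <- unclass(model$mean)
  seg <- p[-1, , drop = FALSE] - p[-nT, , drop = FALSE]
  slen <- sqrt(rowSums(seg^2))
  L <- sum(slen)
  pn <- p / L
  ## forward pass (mirrors curve_to_srvf + apply_prior_state + inv_exp_map)
  vc <- stencil_deriv(pn)
  sp <- sqrt(rowSums(vc^2))
  q0 <- vc / sqrt(sp)
  nq0 <- sqrt(sum(w * rowSums(q0^2)))
  q <- q0 / nq0
  qr <- q %*% t(state$rotation)
  gam <- clamp(state$gamma, 0, 1)
  gd <- pmax(as.vector(stencil_deriv(matrix(state$gamma, ncol = 1))), 1e-8)
  tg <- seq(0, 1, length.out = nT)
  ## linear-interpolation operator rows: indices and weights
  u_pos <- clamp(gam, 0, 1) * (nT - 1) + 1
  i0 <- pmin(pmax(floor(u_pos), 1), nT - 1)
  wi <- u_pos - i0
  qg <- (1 - wi) * qr[i0, , drop = FALSE] + wi * qr[i0 + 1, , drop = FALSE]
  qg <- qg * sqrt(gd)
  nqg <- sqrt(sum(w * rowSums(qg^2)))
  qa <- qg / nqg
  ip <- clamp(sum(w * rowSums(mu * qa)), -1, 1)
  theta <- acos(ip)
  if (theta < 1e-12) return(matrix(0, nT, 2))
  uu <- qa - ip * mu
  nu <- sqrt(sum(w * rowSums(uu^2)))
  v <- theta * uu / nu
  sp_mod <- model_split(model, v)
  ## dE/dv in the weighted metric
  wv <- Reduce(`+`, lapply(seq_len(model$m), function(j)
    (sp_mod$coef[j] / model$S[j]) * model$U[, , j])) +
    sp_mod$vperp / model$delta^2
  ## backward pass
  alpha <- sum(w * rowSums(wv * uu))
  wv_mu <- sum(w * rowSums(wv * mu))
  g_qa <- (theta / nu) * wv - (theta * alpha / nu^3) * uu +
    (-alpha / (nu * sqrt(max(1 - ip^2, 1e-12))) - (theta / nu) * wv_mu) * mu
  ## normalize adjoint (qa = qg/nqg)
  g_qg <- g_qa / nqg - (sum(w * rowSums(g_qa * qg)) / nqg^3) * qg
  ## warp adjoint: qg_t = sqrt(gd_t) * interp(qr)(gam_t)
  coefs <- w * sqrt(gd)
  g_qr <- matrix(0, nT, 2)
  for (col in 1:2) {
    contrib <- coefs * g_qg[, col]
    acc <- numeric(nT)
    for (s in seq_len(nT)) {
      acc[i0[s]] <- acc[i0[s]] + (1 - wi[s]) * contrib[s]
      acc[i0[s] + 1] <- acc[i0[s] + 1] + wi[s] * contrib[s]
    }
    g_qr[, col] <- acc
  }
  g_qr <- g_qr / w
  ## rotation adjoint
  g_q <- g_qr %*% state$rotation
  ## normalize adjoint (q = q0/nq0)
  g_q0 <- g_q / nq0 - (sum(w * rowSums(g_q * q0)) / nq0^3) * q0
  ## q0 = vc/sqrt(sp): per-row (I - nn'/2)/sqrt(sp) pullback
  nvec <- vc / sp
  hrow <- (g_q0 - 0.5 * rowSums(g_q0 * nvec) * nvec) / sqrt(sp)
  ## stencil-derivative adjoint of w*hrow (Euclidean gradient wrt pn)
  wh <- w * hrow
  h <- 1 / (nT - 1)
  g_pn <- matrix(0, nT, 2)
  g_pn[3:nT, ] <- g_pn[3:nT, ] + wh[2:(nT - 1), , drop = FALSE] / (2 * h)
  g_pn[1:(nT - 2), ] <- g_pn[1:(nT - 2), ] - wh[2:(nT - 1), , drop = FALSE] / (2 * h)
  g_pn[1, ] <- g_pn[1, ] - 3 * wh[1, ] / (2 * h)
  g_pn[2, ] <- g_pn[2, ] + 4 * wh[1, ] / (2 * h)
  g_pn[3, ] <- g_pn[3, ] - wh[1, ] / (2 * h)
  g_pn[nT, ] <- g_pn[nT, ] + 3 * wh[nT, ] / (2 * h)
  g_pn[nT - 1, ] <- g_pn[nT - 1, ] - 4 * wh[nT, ] / (2 * h)
  g_pn[nT - 2, ] <- g_pn[nT - 2, ] + wh[nT, ] / (2 * h)
  ## pn = p/L adjoint
  useg <- seg / slen
  dLdp <- rbind(-useg[1, , drop = FALSE],
                useg[-(nT - 1), , drop = FALSE] - useg[-1, , drop = FALSE],
                useg[nT - 1, , drop = FALSE])
  kap <- sum(g_pn * p)
  G <- g_pn / L - (kap / L^2) * dLdp
  G / w
}

#' Write / read a fitted shape model (versioned JSON)
#'
#' Plain-text JSON with full-precision arrays: header (`schema`, `T`, `m`,
#' `delta`, `n_train`, optional `seed`) plus `mean`, `U`, `S`.
#'
#' @param model a `bt_shape_model`.
#' @param path output path.
#' @param seed optional creation seed recorded for provenance.
#' @return `path` invisibly (write); a `bt_shape_model` (read).
#' @export
write_shape_model <- function(model, path, seed = NULL) {
  obj <- list(schema = "bayestract-shape-model/1",
              T = nrow(model$mean), m = model$m, delta = model$delta,
              n_train = model$n_train, seed = seed,
              mean = unclass(model$mean), U = model$U, S = model$S,
              all_S = model$all_S)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "bayestract-shape-model/1"))
    stop("unrecognized shape-model schema: ", obj$schema)
  mu <- matrix(obj$mean, ncol = 2)
  class(mu) <- c("bt_srvf", "matrix", "array")
  structure(list(mean = mu,
                 U = array(obj$U, c(obj$T, 2, obj$m)),
                 S = as.numeric(obj$S), delta = obj$delta, m = obj$m,
                 n_train = obj$n_train, all_S = as.numeric(obj$all_S)),
            class = "bt_shape_model")
}
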