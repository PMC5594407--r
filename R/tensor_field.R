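## Tensor fields are stored channelwise: G1 x G2 x 3 arrays with channels
## (Mxx, Mxy, Myy). Node (i, j) (1-based) sits at ((i-1/2)/G1, (j-1/2)/G2),
## i.e. a node-centered grid whose cells tile [0,1]^2. All caches (inverse
## field, central-difference spatial gradients of M and M^-1) are built at
## construction.

## Largest/smallest eigenvalue of symmetric 2x2 tensors, vectorized over
## channel vectors (a = xx, b = xy, c = yy).
eig2_range <- function(a, b, c) {
  m <- (a + c) / 2
  r <- sqrt(((a - c) / 2)^2 + b^2)
  list(lo = m - r, hi = m + r)
}

## Floor eigenvalues of symmetric 2x2 tensors at eps, channelwise arrays.
floor_eigs <- function(a, b, c, eps) {
  m <- (a + c) / 2
  dd <- (a - c) / 2
  r <- sqrt(dd^2 + b^2)
  l1 <- m + r; l2 <- m - r
  need <- which(l2 < eps | l1 < eps)
  if (length(need)) {
    ## eigenvector for l1: (cos t, sin t) with t = atan2(b, dd)/... use
    ## direct formula: v1 ∝ (b, l1 - a) unless b == 0.
    for (k in need) {
      S <- matrix(c(a[k], b[k], b[k], c[k]), 2, 2)
      e <- eigen(S, symmetric = TRUE)
      lam <- pmax(e$values, eps)
      S2 <- e$vectors %*% diag(lam) %*% t(e$vectors)
      a[k] <- S2[1, 1]; b[k] <- S2[1, 2]; c[k] <- S2[2, 2]
    }
  }
  list(a = a, b = b, c = c)
}

## Central differences of a G1 x G2 matrix on the node grid (spacing 1/G1,
## 1/G2 in domain units), one-sided at the edges.
grid_gradient <- function(z, g1, g2) {
  dx <- z; dy <- z
  if (g1 >= 3) {
    dx[2:(g1 - 1), ] <- (z[3:g1, ] - z[1:(g1 - 2), ]) * (g1 / 2)
    dx[1, ] <- (z[2, ] - z[1, ]) * g1
    dx[g1, ] <- (z[g1, ] - z[g1 - 1, ]) * g1
  } else dx[] <- 0
  if (g2 >= 3) {
    dy[, 2:(g2 - 1)] <- (z[, 3:g2] - z[, 1:(g2 - 2)]) * (g2 / 2)
    dy[, 1] <- (z[, 2] - z[, 1]) * g2
    dy[, g2] <- (z[, g2] - z[, g2 - 1]) * g2
  } else dy[] <- 0
  list(dx = dx, dy = dy)
}

#' Gridded field of 2x2 symmetric positive-definite tensors
#'
#' Constructs a tensor field over the unit square from a `G1 x G2 x 3` array
#' of channels `(Mxx, Mxy, Myy)`. Node `(i, j)` is centered at
#' `((i-1/2)/G1, (j-1/2)/G2)`. Eigenvalues are floored at
#' `eps_rel * max eigenvalue` so every node is safely invertible; the inverse
#' field and the central-difference spatial gradients of both `M` and `M^-1`
#' are cached.
#'
#' @param channels numeric `G1 x G2 x 3` array, channels `Mxx, Mxy, Myy`.
#' @param eps_rel relative eigenvalue floor (default `1e-4`).
#' @return object of class `bt_tensor_field`.
#' @export
bt_tensor_field <- function(channels, eps_rel = 1e-4) {
  ch <- channels
  if (length(dim(ch)) != 3L || dim(ch)[3] != 3L)
    stop("channels must be a G1 x G2 x 3 array (Mxx, Mxy, Myy)")
  g1 <- dim(ch)[1]; g2 <- dim(ch)[2]
  a <- ch[, , 1]; b <- ch[, , 2]; c <- ch[, , 3]
  if (anyNA(ch) || any(!is.finite(ch))) stop("non-finite tensor entry")
  hi <- eig2_range(a, b, c)$hi
  lam_max <- max(hi)
  if (lam_max <= 0) stop("tensor field has no positive eigenvalue")
  eps <- eps_rel * lam_max
  lo <- eig2_range(a, b, c)$lo
  if (any(lo < -0.5 * lam_max))
    stop("non-SPD tensor entry: strongly negative eigenvalue in input")
  fl <- floor_eigs(a, b, c, eps)
  a <- fl$a; b <- fl$b; c <- fl$c
  det <- a * c - b^2
  ia <- c / det; ib <- -b / det; ic <- a / det
  gM <- lapply(list(xx = a, xy = b, yy = c), grid_gradient, g1 = g1, g2 = g2)
  gI <- lapply(list(xx = ia, xy = ib, yy = ic), grid_gradient, g1 = g1, g2 = g2)
  structure(list(
    g1 = g1, g2 = g2, eps = eps,
    M = list(xx = a, xy = b, yy = c),
    Minv = list(xx = ia, xy = ib, yy = ic),
    ## gradients: [[channel]]$dx / $dy, channel order xx, xy, yy
    gradM = gM, gradMinv = gI), class = "bt_tensor_field")
}

#' @export
print.bt_tensor_field <- function(x, ...) {
  cat(sprintf("<bt_tensor_field: %d x %d grid, eigen floor %.3g>\n",
              x$g1, x$g2, x$eps))
  invisible(x)
}

## Bilinear interpolation weights for query points (n x 2) on the node grid.
## Queries outside [0,1]^2 raise; inside, continuous node coordinates are
## clamped to the node-center hull (constant extension in the half-cell rim).
bilinear_nodes <- function(field, xy) {
  xy <- matrix(xy, ncol = 2)
  if (any(xy < -1e-12) || any(xy > 1 + 1e-12))
    stop("query point outside the [0,1]^2 domain")
  u <- clamp(xy[, 1] * field$g1 + 0.5, 1, field$g1)
  v <- clamp(xy[, 2] * field$g2 + 0.5, 1, field$g2)
  i0 <- pmin(floor(u), field$g1 - 1); j0 <- pmin(floor(v), field$g2 - 1)
  if (field$g1 == 1L) i0 <- rep(1, nrow(xy))
  if (field$g2 == 1L) j0 <- rep(1, nrow(xy))
  ## inside_x/y: FALSE where the query fell in the clamped half-cell rim,
  ## so the interpolant is locally constant in that coordinate
  list(i0 = i0, j0 = j0, i1 = pmin(i0 + 1, field$g1), j1 = pmin(j0 + 1, field$g2),
       wx = u - i0, wy = v - j0,
       inside_x = (xy[, 1] * field$g1 + 0.5) > 1 &
                  (xy[, 1] * field$g1 + 0.5) < field$g1,
       inside_y = (xy[, 2] * field$g2 + 0.5) > 1 &
                  (xy[, 2] * field$g2 + 0.5) < field$g2)
}

## Interpolate one channel matrix at prepared weights.
interp_channel <- function(z, w, g1) {
  idx <- function(i, j) (j - 1) * g1 + i
  z <- as.vector(z)
  (1 - w$wx) * (1 - w$wy) * z[idx(w$i0, w$j0)] +
    w$wx * (1 - w$wy) * z[idx(w$i1, w$j0)] +
    (1 - w$wx) * w$wy * z[idx(w$i0, w$j1)] +
    w$wx * w$wy * z[idx(w$i1, w$j1)]
}

## Exact spatial derivative of the bilinear interpolant of one channel at
## prepared weights; zero in the clamped rim (constant extension). This is
## the derivative the discrete energy actually sees, used by the analytic
## energy gradients; field_gradient_at() exposes the cached node-stencil
## gradient instead.
interp_channel_grad <- function(z, w, g1, g2) {
  idx <- function(i, j) (j - 1) * g1 + i
  z <- as.vector(z)
  dx <- g1 * ((1 - w$wy) * (z[idx(w$i1, w$j0)] - z[idx(w$i0, w$j0)]) +
                w$wy * (z[idx(w$i1, w$j1)] - z[idx(w$i0, w$j1)]))
  dy <- g2 * ((1 - w$wx) * (z[idx(w$i0, w$j1)] - z[idx(w$i0, w$j0)]) +
                w$wx * (z[idx(w$i1, w$j1)] - z[idx(w$i1, w$j0)]))
  list(dx = dx * w$inside_x, dy = dy * w$inside_y)
}

## Interpolant-exact gradients of all channels of M or M^-1 at query points.
interp_gradient_exact <- function(field, xy, which = c("M", "Minv")) {
  which <- match.arg(which)
  w <- bilinear_nodes(field, xy)
  lapply(field[[which]], interp_channel_grad, w = w, g1 = field$g1,
         g2 = field$g2)
}

## Vectorized tensor interpolation: returns list(xx, xy, yy) over query rows.
interp_tensor_channels <- function(field, xy, which = c("M", "Minv")) {
  which <- match.arg(which)
  w <- bilinear_nodes(field, xy)
  src <- field[[which]]
  out <- lapply(src, interp_channel, w = w, g1 = field$g1)
  fl <- floor_eigs(out$xx, out$xy, out$yy, field$eps)
  list(xx = fl$a, xy = fl$b, yy = fl$c)
}

## Vectorized gradient interpolation: returns list with [[channel]]$dx/$dy.
interp_gradient_channels <- function(field, xy, which = c("M", "Minv")) {
  which <- match.arg(which)
  w <- bilinear_nodes(field, xy)
  src <- if (which == "M") field$gradM else field$gradMinv
  lapply(src, function(g) list(
    dx = interp_channel(g$dx, w, field$g1),
    dy = interp_channel(g$dy, w, field$g1)))
}

#' Interpolate a tensor at a domain point
#'
#' Entrywise bilinear interpolation over the four enclosing nodes, followed
#' by symmetrization (implicit in the channel storage) and eigenvalue
#' flooring. At a grid node the node tensor is returned exactly.
#'
#' @param field a [bt_tensor_field()].
#' @param x length-2 domain point in `[0,1]^2`.
#' @return 2x2 symmetric positive-definite matrix.
#' @export
interpolate_tensor <- function(field, x) {
  ch <- interp_tensor_channels(field, matrix(x, ncol = 2), "M")
  matrix(c(ch$xx, ch$xy, ch$xy, ch$yy), 2, 2)
}

#' Spatial gradient of the tensor field at a point
#'
#' Bilinear interpolation of the cached central-difference gradient of `M`
#' or of `M^-1`. The result is a `2 x 2 x 2` array `A` with
#' `A[, , k] = d(field)/dx_k`, in tensor units per domain unit.
#'
#' @param field a [bt_tensor_field()].
#' @param x length-2 domain point.
#' @param which `"M"` or `"M_inverse"`.
#' @return `2 x 2 x 2` array.
#' @export
field_gradient_at <- function(field, x, which = c("M", "M_inverse")) {
  which <- match.arg(which)
  g <- interp_gradient_channels(field, matrix(x, ncol = 2),
                                if (which == "M") "M" else "Minv")
  A <- array(0, c(2, 2, 2))
  A[, , 1] <- matrix(c(g$xx$dx, g$xy$dx, g$xy$dx, g$yy$dx), 2, 2)
  A[, , 2] <- matrix(c(g$xx$dy, g$xy$dy, g$xy$dy, g$yy$dy), 2, 2)
  A
}

#' Contraction of a 2x2x2 gradient tensor with a vector
#'
#' `tensor_contract(A, x)` is `x[1]*A[,,1] + x[2]*A[,,2]`;
#' `tensor_transpose(A)` swaps the first and third indices, so that
#' `tensor_contract(tensor_transpose(A), n) %*% n` has `i`-th entry
#' `n' A[,,i] n`.
#'
#' @param A `2 x 2 x 2` array.
#' @param x length-2 vector.
#' @return 2x2 matrix.
#' @export
tensor_contract <- function(A, x) x[1] * A[, , 1] + x[2] * A[, , 2]

#' @rdname tensor_contract
#' @export
tensor_transpose <- function(A) aperm(A, c(3, 2, 1))

#' 2D anisotropy index of a tensor
#'
#' `(l1 - l2)/sqrt(l1^2 + l2^2)` for eigenvalues `l1 >= l2 >= 0`; the planar
#' analog of fractional anisotropy, in `[0, 1)`.
#'
#' @param t 2x2 symmetric positive-definite matrix.
#' @return scalar in `[0, 1)`.
#' @export
anisotropy_index <- function(t) {
  t <- as.matrix(t)
  if (any(abs(t - base::t(t)) > 1e-8 * max(1, abs(t))))
    stop("tensor must be symmetric")
  e <- eig2_range(t[1, 1], t[1, 2], t[2, 2])
  if (e$lo < 0) stop("tensor must be positive semi-definite")
  (e$hi - e$lo) / sqrt(e$hi^2 + e$lo^2)
}

## Vectorized anisotropy from channels.
anisotropy_channels <- function(a, b, c) {
  e <- eig2_range(a, b, c)
  (e$hi - e$lo) / sqrt(e$hi^2 + e$lo^2)
}
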