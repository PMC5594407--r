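## Shared fixtures: everything is generated in code at test time.

## half-sine arc between two x-abscissae at height y0, bowing by h
fix_arc <- function(h, n = 80, y0 = 0.3, x0 = 0.1, x1 = 0.9) {
  tt <- seq(0, 1, length.out = n)
  bt_curve(cbind(x0 + (x1 - x0) * tt, y0 + h * sin(pi * tt)))
}

## closed-ish circle polyline of radius r (open curve, endpoints meet)
fix_circle <- function(r, n = 400, center = c(0.5, 0.5)) {
  tt <- seq(0, 2 * pi, length.out = n)
  bt_curve(cbind(center[1] + r * cos(tt), center[2] + r * sin(tt)))
}

## constant tensor field from a single 2x2 symmetric matrix
fix_const_field <- function(M, g = 10) {
  arr <- array(0, c(g, g, 3))
  arr[, , 1] <- M[1, 1]; arr[, , 2] <- M[1, 2]; arr[, , 3] <- M[2, 2]
  bt_tensor_field(arr)
}

## random band-limited scalar function on the unit square
fix_smooth_fun <- function(seed, lo, amp) {
  set.seed(seed)
  a <- rnorm(6, 0, amp)
  function(x, y) lo + a[1] * sin(2 * pi * x) * cos(2 * pi * y) +
    a[2] * cos(2 * pi * x) + a[3] * sin(2 * pi * y) + a[4] * x * y +
    a[5] * x + a[6] * y
}

## random smooth SPD tensor field (entries are band-limited functions)
fix_smooth_tensor_field <- function(seed, g = 24) {
  fxx <- fix_smooth_fun(seed, 1.5, 0.15)
  fyy <- fix_smooth_fun(seed + 50, 1.5, 0.15)
  fxy <- fix_smooth_fun(seed + 99, 0, 0.1)
  xs <- ((1:g) - 0.5) / g
  arr <- array(0, c(g, g, 3))
  arr[, , 1] <- outer(xs, xs, fxx)
  arr[, , 2] <- outer(xs, xs, fxy)
  arr[, , 3] <- outer(xs, xs, fyy)
  bt_tensor_field(arr)
}

## random smooth single-lobe ODF field (lobe angle and sharpness vary
## smoothly over the grid)
fix_smooth_odf_field <- function(seed, g = 16, L = 8) {
  set.seed(seed)
  nt <- 128
  theta <- 2 * pi * (0:(nt - 1)) / nt
  xs <- ((1:g) - 0.5) / g
  alpha <- fix_smooth_fun(seed + 7, 0, 0.5)
  kap <- fix_smooth_fun(seed + 13, 4, 0.8)
  samples <- array(0, c(g, g, nt))
  for (i in 1:g) for (j in 1:g) {
    f <- exp(max(1, kap(xs[i], xs[j])) * cos(2 * (theta - alpha(xs[i], xs[j]))))
    samples[i, j, ] <- f / (sum(f) * 2 * pi / nt)
  }
  bt_odf_field(samples = samples, L = L)
}

## random smooth curve through the domain interior
fix_smooth_curve <- function(seed, n = 150) {
  set.seed(seed)
  tt <- seq(0, 1, length.out = n)
  a <- rnorm(2, 0, 0.04); ph <- runif(2, 0, 2 * pi)
  p0 <- runif(2, 0.15, 0.35); p1 <- runif(2, 0.65, 0.85)
  bt_curve(cbind(p0[1] + tt * (p1[1] - p0[1]) + a[1] * sin(2 * pi * tt + ph[1]),
                 p0[2] + tt * (p1[2] - p0[2]) + a[2] * sin(2 * pi * tt + ph[2])))
}

## central-finite-difference gradient of an energy with respect to curve
## points, divided by the trapezoid weights (comparable to the analytic L2
## gradients); checks a random subset of interior indices
fd_gradient <- function(efun, curve, idx, eps = 1e-6) {
  p <- unclass(curve)
  n <- nrow(p)
  h <- 1 / (n - 1)
  w <- rep(h, n); w[c(1, n)] <- h / 2
  FD <- matrix(0, length(idx), 2)
  for (r in seq_along(idx)) for (k in 1:2) {
    pp <- p; pp[idx[r], k] <- p[idx[r], k] + eps
    pm <- p; pm[idx[r], k] <- p[idx[r], k] - eps
    FD[r, k] <- (efun(bt_curve(pp, validate = FALSE)) -
                   efun(bt_curve(pm, validate = FALSE))) / (2 * eps) / w[idx[r]]
  }
  FD
}

rel_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

## indices whose points are safely away from interpolation-cell boundaries
## (the bilinear interpolant is non-differentiable exactly on them)
fd_safe_idx <- function(curve, idx, g1, g2, margin = 1e-3) {
  p <- unclass(curve)
  fx <- p[idx, 1] * g1 + 0.5
  fy <- p[idx, 2] * g2 + 0.5
  ok <- abs(fx - round(fx)) > margin & abs(fy - round(fy)) > margin
  idx[ok]
}
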