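## Synthetic ground-truth scenes and their rasterized tensor / ODF fields.
## Every generator is a pure function of (parameters, seed): the seed is
## applied locally so scenes are reproducible bit for bit.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## arc from (x0, y0) to (x1, y1) bowing by height h (half-sine), n samples
arc_curve <- function(x0, y0, x1, y1, h, n = 200L) {
  tt <- seq(0, 1, length.out = n)
  base <- cbind(x0 + tt * (x1 - x0), y0 + tt * (y1 - y0))
  dir <- c(-(y1 - y0), x1 - x0); dir <- dir / sqrt(sum(dir^2))
  p <- base + outer(h * sin(pi * tt), dir)
  p[, 1] <- clamp(p[, 1], 0.005, 0.995); p[, 2] <- clamp(p[, 2], 0.005, 0.995)
  bt_curve(p)
}

default_scene_params <- function(kind) {
  switch(kind,
    crossing = list(n_truth = 5L, y0 = 0.15, dy = 0.13, h = 0.04,
                    x0 = 0.08, x1 = 0.92, jitter_y0 = 0.02, jitter_h = 0.003,
                    n_cross = 2L, cross_x = 0.44, cross_dx = 0.03,
                    cross_y = 0.42, cross_slope = 0,
                    cross_y_range = c(0.06, 0.94)),
    kissing = list(n_per_bundle = 3L, gap = 0.04, h = 0.2,
                   x0 = 0.08, x1 = 0.92),
    noisy_patch = list(n_truth = 3L, y0 = 0.40, dy = 0.05, h = 0.10,
                       x0 = 0.08, x1 = 0.92,
                       box = c(0.4, 0.6, 0.35, 0.65)),
    arc_bundle = list(n = 30L, y0 = 0.33, h = 0.04, x0 = 0.08, x1 = 0.92,
                      sd_y0 = 0.015, sd_h = 0.01, sd_end = 0.008),
    stop("unknown scene kind: ", kind))
}

#' Generate a synthetic ground-truth scene
#'
#' Scene kinds: `"crossing"` (an arc bundle crossed near its apex by a
#' bundle of steep straight lines), `"kissing"` (two arc bundles that
#' approach within a grid cell without touching), `"noisy_patch"` (one arc
#' bundle plus a box in which tensors will be randomized), and
#' `"arc_bundle"` (N perturbed arcs sharing endpoint neighborhoods —
#' training data for the shape prior). Deterministic given `seed`.
#'
#' @param kind scene kind.
#' @param params named list overriding the kind's default geometry
#'   parameters.
#' @param seed integer seed.
#' @param n_samples points per generated truth curve.
#' @return object of class `bt_scene`: `kind`, `bundles` (named lists of
#'   [bt_curve()]), `truth` (name of the bundle that plays ground truth),
#'   `params`, `seed`.
#' @export
make_scene <- function(kind = c("crossing", "kissing", "noisy_patch", "arc_bundle"),
                       params = list(), seed = 1L, n_samples = 200L) {
  kind <- match.arg(kind)
  p <- utils::modifyList(default_scene_params(kind), params)
  bundles <- with_seed(seed, switch(kind,
    crossing = {
      ## whole-bundle placement/curvature jitter makes each seed's phantom
      ## a distinct draw from the same family
      y0s <- p$y0 + runif(1, -p$jitter_y0, p$jitter_y0)
      hs <- p$h + runif(1, -p$jitter_h, p$jitter_h)
      A <- lapply(seq_len(p$n_truth) - 1L, function(k)
        arc_curve(p$x0, y0s + k * p$dy, p$x1, y0s + k * p$dy, hs, n_samples))
      B <- lapply(seq_len(p$n_cross) - 1L, function(k) {
        xc <- p$cross_x + k * p$cross_dx
        ys <- seq(p$cross_y_range[2], p$cross_y_range[1],
                  length.out = n_samples)
        bt_curve(cbind(clamp(xc + p$cross_slope * (ys - p$cross_y),
                             0.005, 0.995), ys))
      })
      list(A = A, B = B)
    },
    kissing = {
      A <- lapply(seq_len(p$n_per_bundle) - 1L, function(k)
        arc_curve(p$x0, 0.5 - p$gap / 2 - p$h - k * 0.03,
                  p$x1, 0.5 - p$gap / 2 - p$h - k * 0.03, p$h, n_samples))
      B <- lapply(seq_len(p$n_per_bundle) - 1L, function(k)
        arc_curve(p$x0, 0.5 + p$gap / 2 + p$h + k * 0.03,
                  p$x1, 0.5 + p$gap / 2 + p$h + k * 0.03, -p$h, n_samples))
      list(A = A, B = B)
    },
    noisy_patch = {
      A <- lapply(seq_len(p$n_truth) - 1L, function(k)
        arc_curve(p$x0, p$y0 + k * p$dy, p$x1, p$y0 + k * p$dy, p$h, n_samples))
      list(A = A)
    },
    arc_bundle = {
      A <- lapply(seq_len(p$n), function(k)
        arc_curve(p$x0 + rnorm(1, 0, p$sd_end),
                  p$y0 + rnorm(1, 0, p$sd_y0),
                  p$x1 + rnorm(1, 0, p$sd_end),
                  p$y0 + rnorm(1, 0, p$sd_y0),
                  p$h + rnorm(1, 0, p$sd_h), n_samples))
      list(A = A)
    }))
  structure(list(kind = kind, bundles = bundles, truth = "A",
                 params = p, seed = as.integer(seed)),
            class = "bt_scene")
}

#' @export
print.bt_scene <- function(x, ...) {
  cat(sprintf("<bt_scene '%s': %s; seed %d>\n", x$kind,
              paste(sprintf("%s(%d)", names(x$bundles),
                            lengths(x$bundles)), collapse = ", "), x$seed))
  invisible(x)
}

## separable Gaussian smoothing of a G1 x G2 matrix, sigma in cells,
## reflected boundary
gaussian_smooth_grid <- function(z, sigma) {
  if (sigma <= 0) return(z)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  smooth1 <- function(m) {      # along rows (first index)
    n <- nrow(m)
    idx <- function(i) pmin(pmax(ifelse(i < 1, 2 - i, i), 1), n)
    out <- 0 * m
    for (s in (-r):r) out <- out + k[s + r + 1] * m[idx(seq_len(n) + s), , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(z))))
}

## Rasterize all bundle segments: per-node weighted outer products plus
## per-cell tangent-angle lists. Each segment midpoint splats its unit
## tangent's outer product onto the 4 surrounding grid nodes with bilinear
## weights (antialiased, so the rasterized ridge centerline follows the
## true curve rather than the cell lattice); the angle lists used for ODF
## lobes keep plain nearest-cell assignment.
rasterize_tangents <- function(scene, g1, g2) {
  oxx <- matrix(0, g1, g2); oxy <- oxx; oyy <- oxx; cnt <- oxx
  angles <- vector("list", g1 * g2)
  for (bundle in scene$bundles) for (cv in bundle) {
    pmat <- unclass(cv)
    mid <- (pmat[-1, , drop = FALSE] + pmat[-nrow(pmat), , drop = FALSE]) / 2
    seg <- pmat[-1, , drop = FALSE] - pmat[-nrow(pmat), , drop = FALSE]
    len <- sqrt(rowSums(seg^2))
    u <- seg / len
    ## bilinear splat on the node-centered grid
    ux <- clamp(mid[, 1] * g1 + 0.5, 1, g1)
    vy <- clamp(mid[, 2] * g2 + 0.5, 1, g2)
    i0 <- pmin(floor(ux), g1 - 1); j0 <- pmin(floor(vy), g2 - 1)
    wx <- ux - i0; wy <- vy - j0
    for (s in seq_along(len)) {
      ii <- c(i0[s], i0[s] + 1, i0[s], i0[s] + 1)
      jj <- c(j0[s], j0[s], j0[s] + 1, j0[s] + 1)
      ww <- c((1 - wx[s]) * (1 - wy[s]), wx[s] * (1 - wy[s]),
              (1 - wx[s]) * wy[s], wx[s] * wy[s])
      for (q in 1:4) {
        oxx[ii[q], jj[q]] <- oxx[ii[q], jj[q]] + ww[q] * u[s, 1]^2
        oxy[ii[q], jj[q]] <- oxy[ii[q], jj[q]] + ww[q] * u[s, 1] * u[s, 2]
        oyy[ii[q], jj[q]] <- oyy[ii[q], jj[q]] + ww[q] * u[s, 2]^2
        cnt[ii[q], jj[q]] <- cnt[ii[q], jj[q]] + ww[q]
      }
    }
    ic <- pmin(pmax(ceiling(mid[, 1] * g1), 1), g1)
    jc <- pmin(pmax(ceiling(mid[, 2] * g2), 1), g2)
    for (s in seq_along(ic)) {
      cell <- (jc[s] - 1) * g1 + ic[s]
      angles[[cell]] <- c(angles[[cell]], atan2(u[s, 2], u[s, 1]))
    }
  }
  list(oxx = oxx, oxy = oxy, oyy = oyy, count = cnt, angles = angles)
}

#' Rasterize a scene to a smoothed tensor field
#'
#' The domain is discretized into a `grid` of cells; within each cell the
#' unit tangents of the truth segments are averaged as outer products
#' `u u'` and mapped to `a_long * (mean outer product) + a_perp * I`. Cells
#' untouched by fibers get `iso_baseline * I`; inside a `noisy_patch`
#' scene's box, tensors are replaced by seeded random SPD matrices. Each
#' matrix entry is then Gaussian-smoothed (`smooth_sigma` in cells) and
#' eigenvalues re-floored.
#'
#' @param scene a [make_scene()] scene.
#' @param grid grid dims, default `c(20, 20)`.
#' @param a_long,a_perp longitudinal/perpendicular diffusivities of fiber
#'   cells (defaults 1.0, 0.1).
#' @param iso_baseline isotropic diffusivity of empty cells (default 0.2).
#' @param smooth_sigma Gaussian sigma in cells (default 0.75).
#' @return a [bt_tensor_field()].
#' @export
scene_to_tensor_field <- function(scene, grid = c(20, 20), a_long = 1.0,
                                  a_perp = 0.1, iso_baseline = 0.2,
                                  smooth_sigma = 0.75) {
  g1 <- grid[1]; g2 <- grid[2]
  ra <- rasterize_tangents(scene, g1, g2)
  occ <- ra$count > 0.5
  den <- ifelse(occ, ra$count, 1)
  xx <- ifelse(occ, a_long * ra$oxx / den + a_perp, iso_baseline)
  xy <- ifelse(occ, a_long * ra$oxy / den, 0)
  yy <- ifelse(occ, a_long * ra$oyy / den + a_perp, iso_baseline)
  if (scene$kind == "noisy_patch") {
    b <- scene$params$box
    cx <- ((seq_len(g1)) - 0.5) / g1; cy <- ((seq_len(g2)) - 0.5) / g2
    inbox <- outer(cx >= b[1] & cx <= b[2], cy >= b[3] & cy <= b[4])
    rnd <- with_seed(scene$seed + 1000L, {
      nfill <- sum(inbox)
      phi <- runif(nfill, 0, pi)
      u1 <- runif(nfill, 0.1, 1); u2 <- runif(nfill, 0.1, 1)
      list(xx = u1 * cos(phi)^2 + u2 * sin(phi)^2,
           xy = (u1 - u2) * sin(phi) * cos(phi),
           yy = u1 * sin(phi)^2 + u2 * cos(phi)^2)
    })
    xx[inbox] <- rnd$xx; xy[inbox] <- rnd$xy; yy[inbox] <- rnd$yy
  }
  arr <- array(0, c(g1, g2, 3))
  arr[, , 1] <- gaussian_smooth_grid(xx, smooth_sigma)
  arr[, , 2] <- gaussian_smooth_grid(xy, smooth_sigma)
  arr[, , 3] <- gaussian_smooth_grid(yy, smooth_sigma)
  bt_tensor_field(arr)
}

#' Rasterize a scene to a smoothed ODF field
#'
#' Each cell's density on the circle is a mixture of antipodally symmetric
#' von Mises-style lobes `exp(sharpness * cos(2 (theta - alpha)))` centered
#' on the tangent angles of the truth segments in that cell (crossing cells
#' naturally get multiple lobes), mixed with a uniform floor; empty cells
#' are uniform. Densities are Gaussian-smoothed across the grid, normalized,
#' and projected on even Fourier harmonics up to order `L`.
#'
#' @param scene a [make_scene()] scene.
#' @param grid grid dims, default `c(20, 20)`.
#' @param sharpness lobe concentration (default 8).
#' @param smooth_sigma Gaussian sigma in cells (default 0.75).
#' @param iso_weight uniform mixture weight in fiber cells (default 0.1).
#' @param L even Fourier truncation order (default 8).
#' @param n_theta angular samples per cell during construction.
#' @return a [bt_odf_field()].
#' @export
scene_to_odf_field <- function(scene, grid = c(20, 20), sharpness = 8,
                               smooth_sigma = 0.75, iso_weight = 0.1,
                               L = 8L, n_theta = 256L) {
  g1 <- grid[1]; g2 <- grid[2]
  ra <- rasterize_tangents(scene, g1, g2)
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  samples <- array(1 / (2 * pi), c(g1, g2, n_theta))
  for (i in seq_len(g1)) for (j in seq_len(g2)) {
    ang <- ra$angles[[(j - 1) * g1 + i]]
    if (is.null(ang)) next
    f <- rep(0, n_theta)
    for (al in ang) {
      lobe <- exp(sharpness * cos(2 * (theta - al)))
      f <- f + lobe / (sum(lobe) * 2 * pi / n_theta)
    }
    f <- f / length(ang)
    samples[i, j, ] <- (1 - iso_weight) * f + iso_weight / (2 * pi)
  }
  if (smooth_sigma > 0)
    for (k in seq_len(n_theta))
      samples[, , k] <- gaussian_smooth_grid(matrix(samples[, , k], g1, g2),
                                             smooth_sigma)
  bt_odf_field(samples = samples, L = L)
}

#' Training shapes from an arc-bundle scene
#'
#' @param scene an `arc_bundle` scene.
#' @param n_points points per resampled training curve.
#' @return list of [bt_curve()] ready for [karcher_mean()] /
#'   [tangent_pca()].
#' @export
make_training_shapes <- function(scene, n_points = 100L) {
  if (scene$kind != "arc_bundle")
    stop("training shapes require an arc_bundle scene")
  lapply(scene$bundles$A, resample_curve, n_out = n_points)
}
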