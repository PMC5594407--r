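test_that("SRVF transform has the stated closed forms and inverts", {
  ## unit-speed unit segment: q = (1, 0) everywhere, unit norm
  seg <- bt_curve(cbind(seq(0, 1, length.out = 60), 0))
  q <- curve_to_srvf(seg)
  expect_equal(unclass(q), cbind(rep(1, 60), 0), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(q_inner(q, q), 1, tolerance = 1e-12)
  ## |q|^2 integrates to the curve length before unit-length normalization
  crv <- fix_arc(0.2, 100)
  L <- curve_length(crv)
  v <- bayestract:::stencil_deriv(unclass(crv))
  qraw <- v / sqrt(sqrt(rowSums(v^2)))     # q = vdot / sqrt(|vdot|)
  w <- bayestract:::trapz_weights(100)
  expect_equal(sum(w * rowSums(qraw^2)), L, tolerance = 1e-3)
  ## round trip reproduces the unit-length curve
  q2 <- curve_to_srvf(crv)
  rec <- srvf_to_curve(q2)
  ref <- sweep(unclass(crv), 2, unclass(crv)[1, ]) / L
  haus <- max(sqrt(rowSums((rec - ref)^2)))
  expect_lt(haus, 1e-3)
})

test_that("alignment recovers orbit members", {
  q1 <- curve_to_srvf(fix_arc(0.25, 100))
  ## rotated copy
  O <- bayestract:::rotation_matrix(0.7)
  al <- align_shapes(q1, unclass(q1) %*% t(O))
  expect_lt(al$distance, 1e-3)
  ## mildly reparameterized copy (slopes within the DP lattice)
  tt <- seq(0, 1, length.out = 100)
  gam <- tt + 0.15 * sin(pi * tt)
  qr <- bayestract:::q_normalize(bayestract:::apply_gamma_srvf(unclass(q1), gam))
  al2 <- align_shapes(q1, qr)
  expect_lt(al2$distance, 1e-2)
  ## gamma(t) = t^2 compresses the start below the sampling resolution: the
  ## pure round trip (apply the warp, then its exact inverse) already loses
  ## this much, and alignment should reach that floor
  gam2 <- tt^2
  qr2 <- bayestract:::q_normalize(bayestract:::apply_gamma_srvf(unclass(q1), gam2))
  floor_q <- bayestract:::q_normalize(
    bayestract:::apply_gamma_srvf(qr2, bayestract:::invert_gamma(gam2)))
  d_floor <- acos(min(q_inner(unclass(q1), floor_q), 1))
  al3 <- align_shapes(q1, qr2, symmetric = TRUE)
  expect_lt(al3$distance, d_floor * 1.2)
})

test_that("reparameterization acts by isometry on SRVF pairs", {
  qa <- unclass(curve_to_srvf(fix_arc(0.2, 100)))
  qb <- unclass(curve_to_srvf(fix_arc(0.35, 100)))
  tt <- seq(0, 1, length.out = 100)
  ag <- bayestract:::apply_gamma_srvf
  for (gam in list(tt + 0.1 * sin(pi * tt), tt + 0.2 * tt * (1 - tt))) {
    d0 <- sqrt(q_inner(qa - qb, qa - qb))
    d1 <- sqrt(q_inner(ag(qa, gam) - ag(qb, gam),
                       ag(qa, gam) - ag(qb, gam)))
    expect_lt(abs(d0 - d1) / d0, 1e-3)
  }
})

test_that("DP matching equals exhaustive search over monotone lattice paths", {
  ## tiny grids: enumerate every monotone path with the same coprime step
  ## set and the same edge cost; the DP must attain the same optimum
  edge_cost <- function(q1, q2, i0, j0, i, j, h) {
    di <- i - i0; dj <- j - j0
    slope <- dj / di
    sq <- sqrt(slope)
    tot <- 0
    n <- nrow(q2)
    for (k in 0:di) {
      w <- if (k == 0 || k == di) 0.5 else 1
      pos <- j0 + slope * k
      p0 <- min(max(pos, 0), n - 1)
      i0p <- min(floor(p0), n - 2)
      wp <- p0 - i0p
      qq <- (1 - wp) * q2[i0p + 1, ] + wp * q2[i0p + 2, ]
      tot <- tot + w * sum((q1[i0 + k + 1, ] - sq * qq)^2)
    }
    tot * h
  }
  exhaustive <- function(q1, q2, max_step = 4L) {
    n <- nrow(q1)
    h <- 1 / (n - 1)
    steps <- expand.grid(di = 1:max_step, dj = 1:max_step)
    steps <- steps[mapply(function(a, b) {
      while (b) { t <- a %% b; a <- b; b <- t }; a
    }, steps$di, steps$dj) == 1, ]
    best <- Inf
    recurse <- function(i, j, acc) {
      if (acc >= best) return()
      if (i == n - 1 && j == n - 1) { best <<- acc; return() }
      for (s in seq_len(nrow(steps))) {
        i2 <- i + steps$di[s]; j2 <- j + steps$dj[s]
        if (i2 <= n - 1 && j2 <= n - 1)
          recurse(i2, j2, acc + edge_cost(q1, q2, i, j, i2, j2, h))
      }
    }
    recurse(0, 0, 0)
    best
  }
  set.seed(8)
  for (n in c(8, 10)) {
    q1 <- unclass(curve_to_srvf(fix_arc(0.2, n)))
    q2 <- unclass(curve_to_srvf(fix_arc(0.32, n, y0 = 0.35)))
    dp <- bayestract:::.dp_align_cpp(q1, q2, 4L)
    expect_equal(dp$cost, exhaustive(q1, q2), tolerance = 1e-12)
  }
})

test_that("sphere geometry: exp/log inverse pair and isometric transport", {
  mu <- unclass(curve_to_srvf(fix_arc(0.25, 80)))
  qb <- unclass(curve_to_srvf(fix_arc(0.4, 80)))
  v <- qb - q_inner(qb, mu) * mu
  v <- 0.3 * v / sqrt(q_inner(v, v))
  expect_equal(unclass(exp_map(mu, v * 0)), mu, tolerance = 1e-12)
  q <- exp_map(mu, v)
  v2 <- inv_exp_map(mu, q, align = FALSE)
  expect_lt(sqrt(q_inner(v - v2, v - v2)) / 0.3, 1e-3)
  w <- bayestract:::q_normalize(qb - q_inner(qb, mu) * mu)
  wb <- parallel_transport(w, mu, q)
  expect_lt(abs(sqrt(q_inner(wb, wb)) - 1), 1e-6)
  expect_lt(abs(q_inner(wb, q)), 1e-10)
  big <- v / 0.3 * 3.2
  expect_error(exp_map(mu, big), "truncation")
})

test_that("Karcher mean: identical shapes, midpoint property, rotation invariance", {
  q <- curve_to_srvf(fix_arc(0.22, 80))
  km <- karcher_mean(list(q, q, q))
  expect_lt(align_shapes(q, km)$distance, 1e-6)
  qa <- curve_to_srvf(fix_arc(0.15, 80))
  qb <- curve_to_srvf(fix_arc(0.35, 80))
  km2 <- suppressWarnings(karcher_mean(list(qa, qb), tol = 1e-4, max_iter = 60))
  d1 <- align_shapes(km2, qa)$distance
  d2 <- align_shapes(km2, qb)$distance
  expect_lt(abs(d1 - d2), 1e-2)
  ## rotating every input leaves the mean shape unchanged
  set.seed(12)
  shapes <- lapply(1:6, function(k) curve_to_srvf(fix_arc(0.2 + 0.03 * k, 80)))
  O <- bayestract:::rotation_matrix(0.9)
  rotated <- lapply(shapes, function(q) {
    qq <- unclass(q) %*% t(O); class(qq) <- class(q); qq
  })
  m1 <- karcher_mean(shapes)
  m2 <- karcher_mean(rotated)
  expect_lt(align_shapes(m1, m2)$distance, 1e-3)
})

test_that("tangent PCA: orthonormal basis, dominant mode, full-rank reconstruction", {
  set.seed(13)
  ## one-dimensional family: single dominant singular value
  shapes <- lapply(1:20, function(k) curve_to_srvf(fix_arc(0.15 + runif(1, 0, 0.2), 80)))
  mdl <- tangent_pca(shapes, m = 3)
  expect_gt(mdl$S[1] / mdl$S[2], 10)
  G <- sapply(1:mdl$m, function(i) sapply(1:mdl$m, function(j)
    q_inner(mdl$U[, , i], mdl$U[, , j])))
  expect_lt(max(abs(G - diag(mdl$m))), 1e-8)
  expect_lt(abs(q_inner(mdl$U[, , 1], unclass(mdl$mean))), 1e-8)
  expect_true(all(diff(mdl$S) <= 0) && all(mdl$S > 0))
  expect_lt(mdl$delta, sqrt(min(mdl$S)))
  ## m = n - 1 basis captures (almost) all variance of the shooting vectors
  small <- lapply(1:8, function(k) curve_to_srvf(fix_arc(0.1 + 0.04 * k, 60)))
  mu <- karcher_mean(small, max_iter = 60)
  mfull <- tangent_pca(small, mean = mu, m = 7)
  vs <- lapply(small, function(q) inv_exp_map(unclass(mu), unclass(q)))
  vbar <- Reduce(`+`, vs) / length(vs)
  tot <- 0; res <- 0
  for (v in vs) {
    vc <- v - vbar
    tot <- tot + q_inner(vc, vc)
    proj <- Reduce(`+`, lapply(1:7, function(j)
      q_inner(vc, mfull$U[, , j]) * mfull$U[, , j]))
    r <- vc - proj
    res <- res + q_inner(r, r)
  }
  expect_lt(res / tot, 1e-6)
  expect_error(tangent_pca(small, mean = mu, m = 20), "exceeds")
})

test_that("tangent PCA recovers a synthetic 2-mode shape model", {
  ## truth: mean arc plus two orthonormal HORIZONTAL tangent directions
  ## (components along the rotation and reparameterization orbit are
  ## projected out first, since alignment removes them by construction)
  base <- curve_to_srvf(fix_arc(0.25, 80))
  mu <- unclass(base)
  n <- 80
  tt <- seq(0, 1, length.out = n)
  mudot <- bayestract:::stencil_deriv(mu)
  vertical <- list(cbind(-mu[, 2], mu[, 1]))          # rotation direction
  for (k in 1:8) {                                    # reparam directions
    b <- sin(k * pi * tt)
    bdot <- k * pi * cos(k * pi * tt)
    vertical <- c(vertical, list(mudot * b + 0.5 * mu * bdot))
  }
  horiz <- function(v) {
    v <- v - q_inner(v, mu) * mu
    for (z in basis_v) v <- v - q_inner(v, z) * z
    v
  }
  basis_v <- list()
  for (z in vertical) {
    z <- z - q_inner(z, mu) * mu
    for (y in basis_v) z <- z - q_inner(z, y) * y
    nz <- sqrt(q_inner(z, z))
    if (nz > 1e-8) basis_v <- c(basis_v, list(z / nz))
  }
  mk_dir <- function(curve) {
    v <- unclass(curve_to_srvf(curve)) - mu
    v <- horiz(v)
    v / sqrt(q_inner(v, v))
  }
  u1 <- mk_dir(fix_arc(0.45, 80))
  u2raw <- mk_dir(bt_curve(cbind(seq(0.1, 0.9, length.out = 80),
                                 0.3 + 0.15 * sin(2 * pi * tt))))
  u2 <- u2raw - q_inner(u2raw, u1) * u1
  u2 <- u2 / sqrt(q_inner(u2, u2))
  s1 <- 0.12; s2 <- 0.05
  set.seed(14)
  shapes <- lapply(1:30, function(k) {
    q <- exp_map(mu, rnorm(1, 0, s1) * u1 + rnorm(1, 0, s2) * u2)
    class(q) <- c("bt_srvf", "matrix", "array")
    q
  })
  mdl <- tangent_pca(shapes, m = 2)
  ## subspace angle between span(U) and span(u1, u2) in the L2 metric
  sw <- sqrt(bayestract:::trapz_weights(80))
  flat <- function(v) as.vector(v * sw)
  Utrue <- qr.Q(qr(cbind(flat(u1), flat(u2))))
  Uhat <- cbind(flat(mdl$U[, , 1]), flat(mdl$U[, , 2]))
  sv <- svd(t(Utrue) %*% Uhat)$d
  angle <- acos(min(pmin(sv, 1))) * 180 / pi
  expect_lt(angle, 10)
  expect_lt(abs(sqrt(mdl$S[1]) - s1) / s1, 0.25)
  expect_lt(abs(sqrt(mdl$S[2]) - s2) / s2, 0.25)
})

test_that("prior energy: zero at the mean, quadratic along modes, tail scale", {
  set.seed(15)
  shapes <- lapply(1:30, function(k)
    curve_to_srvf(fix_arc(0.22 + rnorm(1, 0, 0.04), 80)))
  mdl <- tangent_pca(shapes)
  expect_equal(e_prior(mdl$mean, mdl), 0, tolerance = 1e-10)
  ## v = s u1 (unaligned evaluation isolates the quadratic form)
  s <- 0.05
  q1 <- exp_map(unclass(mdl$mean), s * mdl$U[, , 1])
  expect_equal(e_prior(q1, mdl, align = FALSE), 0.5 * s^2 / mdl$S[1],
               tolerance = 1e-6)
  ## v orthogonal to the retained modes: pure tail
  set.seed(16)
  r <- matrix(rnorm(160), 80, 2)
  mu <- unclass(mdl$mean)
  v <- r - q_inner(r, mu) * mu
  for (j in seq_len(mdl$m)) v <- v - q_inner(v, mdl$U[, , j]) * mdl$U[, , j]
  v <- 0.1 * v / sqrt(q_inner(v, v))
  q2 <- exp_map(mu, v)
  expect_equal(e_prior(q2, mdl, align = FALSE), 0.5 * 0.01 / mdl$delta^2,
               tolerance = 1e-4)
  expect_gte(e_prior(q2, mdl), 0)
})

test_that("prior energy is invariant over the input's orbit", {
  set.seed(17)
  shapes <- lapply(1:20, function(k)
    curve_to_srvf(fix_arc(0.2 + rnorm(1, 0, 0.03), 100)))
  mdl <- tangent_pca(shapes)
  crv <- fix_arc(0.3, 100)
  e0 <- e_prior_curve(crv, mdl)
  ## rotated copy of the curve
  O <- bayestract:::rotation_matrix(0.5)
  pr <- sweep(unclass(crv), 2, c(0.5, 0.4)) %*% t(O)
  pr <- sweep(pr * 0.5, 2, c(0.5, 0.5), `+`)
  e1 <- e_prior_curve(bt_curve(pr), mdl)
  expect_lt(abs(e1 - e0) / max(e0, 1), 2e-2)
  ## mildly reparameterized copy of the same geometry
  tt <- seq(0, 1, length.out = 100)
  p <- unclass(crv)
  gam <- tt + 0.1 * sin(pi * tt)
  p2 <- cbind(approx(tt, p[, 1], xout = gam)$y, approx(tt, p[, 2], xout = gam)$y)
  e2 <- e_prior_curve(bt_curve(p2), mdl)
  ## the reparameterization residual of the discrete alignment is amplified
  ## by the tail precision, so the invariance is looser than for rotations
  expect_lt(abs(e2 - e0) / max(e0, 1), 0.1)
})

test_that("prior gradient: stationary at the mean, descent, convergence to the mean", {
  set.seed(18)
  n <- 400   # fine sampling so the transform round-trip error is negligible
  shapes <- lapply(1:30, function(k)
    curve_to_srvf(fix_arc(0.22 + rnorm(1, 0, 0.04), n)))
  mdl <- tangent_pca(shapes)
  mu_curve <- bt_curve(srvf_to_curve(mdl$mean, origin = c(0.1, 0.35),
                                     scale = 0.8))
  G <- grad_e_prior_curve(mu_curve, mdl)
  expect_lt(sqrt(mean(rowSums(G^2))), 1e-3)
  ## one small step along -gradient decreases the prior on 20 random curves
  set.seed(19)
  n2 <- 100
  shapes2 <- lapply(1:30, function(k)
    curve_to_srvf(fix_arc(0.22 + rnorm(1, 0, 0.04), n2)))
  mdl2 <- tangent_pca(shapes2)
  ok <- 0
  for (k in 1:20) {
    crv <- fix_arc(runif(1, -0.1, 0.45), n2, y0 = runif(1, 0.2, 0.4))
    e0 <- e_prior_curve(crv, mdl2)
    G <- grad_e_prior_curve(crv, mdl2)
    step <- 1e-4 / max(sqrt(rowSums(G^2)))
    e1 <- e_prior_curve(bt_curve(unclass(crv) - step * G, validate = FALSE),
                        mdl2)
    ok <- ok + (e1 < e0)
  }
  expect_gte(ok, 19)
  ## pure-prior evolution pulls a straight line onto the mean shape, with
  ## the shape distance to the mean decreasing monotonically across the
  ## checked stages
  crv <- bt_curve(cbind(seq(0.1, 0.9, length.out = n2), 0.35))
  ep <- e_prior_curve(crv, mdl2)
  dists <- align_shapes(mdl2$mean, curve_to_srvf(crv))$distance
  for (it in 1:150) {
    G <- grad_e_prior_curve(crv, mdl2)
    G[c(1, n2), ] <- 0
    gn <- max(sqrt(rowSums(G^2)))
    p <- unclass(crv) - min(2e-3, 1e-2 / gn) * G
    cand <- bt_curve(clamp(p, 0, 1), validate = FALSE)
    e2 <- e_prior_curve(cand, mdl2)
    if (e2 < ep) { crv <- cand; ep <- e2 }
    if (it %% 50 == 0)
      dists <- c(dists, align_shapes(mdl2$mean, curve_to_srvf(crv))$distance)
  }
  expect_true(all(diff(dists) < 1e-6))
  expect_lt(dists[length(dists)], 0.05)
})

test_that("shape model files round-trip through JSON", {
  set.seed(20)
  shapes <- lapply(1:10, function(k)
    curve_to_srvf(fix_arc(0.2 + 0.02 * k, 60)))
  mdl <- tangent_pca(shapes)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_shape_model(mdl, tmp, seed = 99)
  back <- read_shape_model(tmp)
  expect_equal(unclass(back$mean), unclass(mdl$mean), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(back$U, mdl$U, tolerance = 1e-14)
  expect_equal(back$S, mdl$S, tolerance = 1e-14)
  expect_equal(back$delta, mdl$delta, tolerance = 1e-14)
  q <- curve_to_srvf(fix_arc(0.3, 60))
  expect_equal(e_prior(q, back), e_prior(q, mdl), tolerance = 1e-10)
})
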