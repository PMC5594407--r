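test_that("curve derivatives reproduce analytic velocity and tangent", {
  ## straight line: constant velocity, zero acceleration
  b <- bt_curve(cbind(seq(0, 1, length.out = 11), 0))
  d <- curve_derivatives(b)
  expect_equal(d$velocity, cbind(rep(1, 11), 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(d$acceleration)), 1e-9)
  expect_equal(d$tangent[, 1], rep(1, 11), tolerance = 1e-12)
  ## circle arc: speed = arc length, tangent perpendicular to the radius
  r <- 0.3
  circ <- fix_circle(r, 400)
  d <- curve_derivatives(circ)
  expect_equal(mean(d$speed[5:395]), 2 * pi * r, tolerance = 1e-3)
  rad <- sweep(unclass(circ), 2, c(0.5, 0.5))
  dots <- rowSums(d$tangent[5:395, ] * rad[5:395, ]) / r
  expect_lt(max(abs(dots)), 1e-3)
  expect_lt(max(abs(sqrt(rowSums(d$tangent^2)) - 1)), 1e-12)
})

test_that("degenerate curves are rejected", {
  expect_error(bt_curve(cbind(c(0, 1), c(0, 0))), "degenerate")
  expect_error(bt_curve(cbind(c(0, 0, 1), c(0, 0, 0))), "degenerate")
  expect_error(bt_curve(cbind(c(0, 2, 1), c(0, 0, 0))), "unit square")
})

test_that("curvature of a circle has magnitude 1/r and points inward", {
  r <- 0.25
  cv <- curvature(fix_circle(r, 500))
  interior <- 5:495
  expect_equal(mean(abs(cv$kappa[interior])), 1 / r, tolerance = 1e-3)
  dirs <- sweep(unclass(fix_circle(r, 500)), 2, c(0.5, 0.5))
  inward <- rowSums(cv$flow * (-dirs))
  expect_true(all(inward[interior] > 0))
})

test_that("tensor interpolation is exact at nodes and bilinear between them", {
  g <- 10
  arr <- array(0, c(g, g, 3))
  set.seed(1)
  arr[, , 1] <- 1 + 0.3 * matrix(runif(g * g), g, g)
  arr[, , 2] <- 0.1 * matrix(runif(g * g, -1, 1), g, g)
  arr[, , 3] <- 1 + 0.3 * matrix(runif(g * g), g, g)
  f <- bt_tensor_field(arr)
  ## node identity
  x <- c((3 - 0.5) / g, (7 - 0.5) / g)
  M <- interpolate_tensor(f, x)
  expect_equal(M[1, 1], f$M$xx[3, 7], tolerance = 1e-12)
  expect_equal(M[1, 2], f$M$xy[3, 7], tolerance = 1e-12)
  ## constant field returns the constant everywhere
  fc <- fix_const_field(diag(c(1, 0.5)))
  set.seed(2)
  for (k in 1:5) {
    M <- interpolate_tensor(fc, runif(2))
    expect_equal(M, diag(c(1, 0.5)), tolerance = 1e-12)
  }
  ## midpoint of two nodes with diag(1, 0.1) and diag(0.1, 1): entrywise mean
  arr2 <- array(0, c(2, 1, 3))
  arr2[1, 1, ] <- c(1, 0, 0.1); arr2[2, 1, ] <- c(0.1, 0, 1)
  f2 <- bt_tensor_field(arr2)
  M <- interpolate_tensor(f2, c(0.5, 0.5))
  expect_equal(M, diag(c(0.55, 0.55)), tolerance = 1e-12)
})

test_that("interpolated tensors stay SPD above the eigenvalue floor", {
  f <- fix_smooth_tensor_field(5)
  set.seed(3)
  xs <- matrix(runif(2000), ncol = 2)
  ch <- bayestract:::interp_tensor_channels(f, xs, "M")
  lo <- bayestract:::eig2_range(ch$xx, ch$xy, ch$yy)$lo
  expect_true(all(lo >= f$eps - 1e-12))
})

test_that("field gradients match hand-differentiated ramps and the inverse identity", {
  ## constant field: zero gradient
  fc <- fix_const_field(diag(c(1.2, 0.7)))
  A <- field_gradient_at(fc, c(0.4, 0.6), "M")
  expect_lt(max(abs(A)), 1e-12)
  ## M = diag(1 + x1, 1): dM/dx1 = diag(1, 0), dM/dx2 = 0
  g <- 20
  xs <- ((1:g) - 0.5) / g
  arr <- array(0, c(g, g, 3))
  arr[, , 1] <- outer(xs, xs, function(x, y) 1 + x)
  arr[, , 3] <- 1
  f <- bt_tensor_field(arr)
  A <- field_gradient_at(f, c(0.5, 0.5), "M")
  expect_equal(A[, , 1], matrix(c(1, 0, 0, 0), 2, 2), tolerance = 1e-8)
  expect_lt(max(abs(A[, , 2])), 1e-8)
  ## matrix-inverse derivative identity at interior nodes:
  ## <<grad M^-1, e1>> = -M^-1 (dM/dx1) M^-1
  fs <- fix_smooth_tensor_field(7)
  for (x in list(c(0.45, 0.55), c(0.3, 0.7))) {
    Ai <- field_gradient_at(fs, x, "M_inverse")
    Am <- field_gradient_at(fs, x, "M")
    Minv <- solve(interpolate_tensor(fs, x))
    lhs <- tensor_contract(Ai, c(1, 0))
    rhs <- -Minv %*% tensor_contract(Am, c(1, 0)) %*% Minv
    expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 2e-2)
  }
})

test_that("cached gradient agrees with differencing the interpolated inverse field", {
  ## grid-scale central differencing of the interpolated inverse field: the
  ## cell-sized step averages over the piecewise-bilinear kinks, which is
  ## the scale at which the cached node-stencil gradient is defined
  g <- 32
  f <- fix_smooth_tensor_field(11, g = g)
  hs <- 1 / g
  set.seed(4)
  for (k in 1:5) {
    x <- runif(2, 0.2, 0.8)
    A <- field_gradient_at(f, x, "M_inverse")
    for (dir in 1:2) {
      e <- c(0, 0); e[dir] <- hs
      Mp <- solve(interpolate_tensor(f, x + e))
      Mm <- solve(interpolate_tensor(f, x - e))
      fd <- (Mp - Mm) / (2 * hs)
      expect_lt(max(abs(A[, , dir] - fd)) / max(1, max(abs(fd))), 1e-2)
    }
  }
})

test_that("tensor transpose-contraction gives the quadratic-form gradient", {
  A <- array(rnorm(8), c(2, 2, 2))
  A[, , 1] <- (A[, , 1] + t(A[, , 1])) / 2
  A[, , 2] <- (A[, , 2] + t(A[, , 2])) / 2
  n <- c(0.6, 0.8)
  v <- tensor_contract(tensor_transpose(A), n) %*% n
  expect_equal(as.numeric(v),
               c(t(n) %*% A[, , 1] %*% n, t(n) %*% A[, , 2] %*% n),
               tolerance = 1e-12)
})

test_that("ODF evaluation: uniform density, lobe ordering, stationary peak", {
  g <- 4
  ## uniform ODF: a0 only
  co <- array(0, c(g, g, bayestract:::odf_n_channels(8)))
  co[, , 1] <- 1 / (2 * pi)
  fu <- bt_odf_field(coefficients = co, L = 8)
  expect_equal(evaluate_odf(fu, c(0.3, 0.3), c(1, 0)), 1 / (2 * pi),
               tolerance = 1e-12)
  expect_equal(evaluate_odf(fu, c(0.3, 0.3), c(0, 1)), 1 / (2 * pi),
               tolerance = 1e-12)
  ## single cos(2 theta) lobe peaked at theta = 0
  co[, , 2] <- 0.1
  fl <- bt_odf_field(coefficients = co, L = 8)
  expect_gt(evaluate_odf(fl, c(0.5, 0.5), c(1, 0)),
            evaluate_odf(fl, c(0.5, 0.5), c(0, 1)))
  ## derivative vanishes at the peak (also check against finite differences)
  expect_lt(abs(evaluate_odf(fl, c(0.5, 0.5), c(1, 0), deriv = 1)), 1e-12)
  eps <- 1e-5
  fd <- (evaluate_odf(fl, c(0.5, 0.5), c(cos(eps), sin(eps))) -
           evaluate_odf(fl, c(0.5, 0.5), c(cos(-eps), sin(-eps)))) / (2 * eps)
  expect_equal(fd, 0, tolerance = 1e-6)
  expect_error(evaluate_odf(fl, c(0.5, 0.5), c(1, 1)), "unit vector")
})

test_that("constructed ODF fields are normalized and antipodally symmetric", {
  f <- fix_smooth_odf_field(3, g = 8)
  nt <- 64
  theta <- 2 * pi * (0:(nt - 1)) / nt
  for (node in list(c(1, 1), c(4, 5), c(8, 8))) {
    co <- matrix(f$coef[node[1], node[2], ], nrow = 1)
    vals <- bayestract:::odf_series_eval(co[rep(1, nt), ], theta, f$L)
    expect_equal(sum(vals) * 2 * pi / nt, 1, tolerance = 1e-6)
    antipodal <- bayestract:::odf_series_eval(co[rep(1, nt), ], theta + pi, f$L)
    expect_lt(max(abs(vals - antipodal)), 1e-10)
    expect_true(all(vals >= -1e-9))
  }
})

test_that("field and fiber files round-trip and reject malformed input", {
  tmp <- tempfile("btio"); dir.create(tmp); on.exit(unlink(tmp, recursive = TRUE))
  f <- fix_smooth_tensor_field(9, g = 12)
  p <- file.path(tmp, "field.nii.gz")
  write_field(f, p)
  f2 <- read_field(p)
  expect_equal(f2$M$xx, f$M$xx, tolerance = 1e-12)
  expect_equal(f2$M$xy, f$M$xy, tolerance = 1e-12)
  fo <- fix_smooth_odf_field(2, g = 6)
  po <- file.path(tmp, "odf.nii.gz")
  write_field(fo, po)
  fo2 <- read_field(po)
  expect_equal(fo2$coef, fo$coef, tolerance = 1e-12)
  ## fibers: order preserved, full precision
  fibers <- list(fix_arc(0.1, 50), fix_arc(-0.05, 50, y0 = 0.6))
  pf <- file.path(tmp, "fibers.tsv")
  write_fibers(fibers, pf)
  back <- read_fibers(pf)
  expect_length(back, 2)
  expect_equal(unclass(back[[1]]), unclass(fibers[[1]]), tolerance = 1e-15)
  expect_equal(unclass(back[[2]]), unclass(fibers[[2]]), tolerance = 1e-15)
  ## malformed fiber file errors name the problem
  writeLines(c("fiber_id\tpoint_index\tx\ty", "1\t1\tfoo\t0.2"),
             file.path(tmp, "bad.tsv"))
  expect_error(read_fibers(file.path(tmp, "bad.tsv")), "malformed")
  ## non-SPD tensor entry in a field file fails validation on read
  arr <- array(0, c(4, 4, 3))
  arr[, , 1] <- 1; arr[, , 3] <- 1
  arr[2, 2, ] <- c(-1, 0, -1)     # strongly negative eigenvalues
  RNifti::writeNifti(RNifti::asNifti(arr), file.path(tmp, "bad.nii.gz"))
  jsonlite::write_json(list(kind = "tensor2"), file.path(tmp, "bad.json"),
                       auto_unbox = TRUE)
  expect_error(read_field(file.path(tmp, "bad.nii.gz")), "non-SPD")
})
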