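#' @useDynLib bayestract, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif approx optim
NULL

## Trapezoidal quadrature on an arbitrary (sorted) abscissa.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## Derivative of columns of a T x k matrix on uniform parameter t in [0,1],
## central differences inside, second-order one-sided stencils at the ends.
stencil_deriv <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 3L) stop("need at least 3 samples for stencil derivatives")
  h <- 1 / (n - 1)
  d <- y
  d[2:(n - 1), ] <- (y[3:n, , drop = FALSE] - y[1:(n - 2), , drop = FALSE]) / (2 * h)
  d[1, ] <- (-3 * y[1, ] + 4 * y[2, ] - y[3, ]) / (2 * h)
  d[n, ] <- (3 * y[n, ] - 4 * y[n - 1, ] + y[n - 2, ]) / (2 * h)
  d
}

## Second derivative, same conventions (first-order one-sided at the ends,
## second-order when n >= 4).
stencil_deriv2 <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 3L) stop("need at least 3 samples for stencil derivatives")
  h2 <- (1 / (n - 1))^2
  d <- y
  d[2:(n - 1), ] <- (y[3:n, , drop = FALSE] - 2 * y[2:(n - 1), , drop = FALSE] +
                       y[1:(n - 2), , drop = FALSE]) / h2
  if (n >= 4L) {
    d[1, ] <- (2 * y[1, ] - 5 * y[2, ] + 4 * y[3, ] - y[4, ]) / h2
    d[n, ] <- (2 * y[n, ] - 5 * y[n - 1, ] + 4 * y[n - 2, ] - y[n - 3, ]) / h2
  } else {
    d[1, ] <- d[2, ]
    d[n, ] <- d[2, ]
  }
  d
}

rot90_ccw <- function(v) cbind(-v[, 2], v[, 1])

rotation_matrix <- function(phi) {
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
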