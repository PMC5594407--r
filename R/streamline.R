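#' Streamline (FACT-style) tracker configuration
#'
#' @param step integration step length in domain units; default one quarter
#'   of a grid cell (resolved against the field at tracking time when `NULL`).
#' @param max_steps per-direction step cap.
#' @param angle_threshold maximum turning angle between consecutive steps,
#'   degrees, in (0, 90].
#' @param anisotropy_floor stop when the local anisotropy index falls below
#'   this (default 0.15).
#' @return list of class `bt_streamline_config`.
#' @export
streamline_config <- function(step = NULL, max_steps = 2000L,
                              angle_threshold = 45, anisotropy_floor = 0.15) {
  if (!is.null(step) && step <= 0) stop("step must be positive")
  if (angle_threshold <= 0 || angle_threshold > 90)
    stop("angle threshold must be in (0, 90] degrees")
  structure(list(step = step, max_steps = as.integer(max_steps),
                 angle_threshold = angle_threshold,
                 anisotropy_floor = anisotropy_floor),
            class = "bt_streamline_config")
}

## principal eigenvector of an interpolated tensor at x (unit 2-vector)
principal_direction <- function(field, x) {
  ch <- interp_tensor_channels(field, matrix(x, ncol = 2), "M")
  a <- ch$xx; b <- ch$xy; c <- ch$yy
  l1 <- eig2_range(a, b, c)$hi
  v <- if (abs(b) > 1e-14) c(b, l1 - a) else if (a >= c) c(1, 0) else c(0, 1)
  v / sqrt(sum(v^2))
}

local_anisotropy <- function(field, x) {
  ch <- interp_tensor_channels(field, matrix(x, ncol = 2), "M")
  anisotropy_channels(ch$xx, ch$xy, ch$yy)
}

## one direction of FACT integration; returns matrix of visited points
## (excluding the seed itself)
fact_half_track <- function(field, seed, dir0, cfg, step) {
  pts <- matrix(0, 0, 2)
  x <- seed; d <- dir0
  cosmax <- cos(cfg$angle_threshold * pi / 180)
  for (k in seq_len(cfg$max_steps)) {
    xn <- x + step * d
    if (any(xn < 0) || any(xn > 1)) break
    if (local_anisotropy(field, xn) < cfg$anisotropy_floor) break
    dn <- principal_direction(field, xn)
    if (sum(dn * d) < 0) dn <- -dn      # sign continuity
    if (sum(dn * d) < cosmax) break     # angle stopping rule
    pts <- rbind(pts, xn)
    x <- xn; d <- dn
  }
  pts
}

#' Deterministic streamline tracking along principal eigenvectors
#'
#' FACT-style fixed-step Euler integration from a seed point, bidirectional
#' along the interpolated principal eigenvector field with sign continuity.
#' Stops at the domain boundary, when the turning angle exceeds the
#' threshold, when the 2D anisotropy index drops below the floor, or at the
#' step cap. Deliberately first-order: the baseline is meant to exhibit the
#' classical failure modes at crossings and noise, not to fix them.
#'
#' @param field a [bt_tensor_field()].
#' @param seed domain point.
#' @param cfg a [streamline_config()].
#' @return a [bt_curve()] (concatenated backward + seed + forward polyline).
#' @export
fact_track <- function(field, seed, cfg = streamline_config()) {
  seed <- as.numeric(seed)
  if (any(seed < 0) || any(seed > 1)) stop("seed outside the domain")
  step <- cfg$step %||% (0.25 / max(field$g1, field$g2))
  d0 <- principal_direction(field, seed)
  fwd <- fact_half_track(field, seed, d0, cfg, step)
  bwd <- fact_half_track(field, seed, -d0, cfg, step)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed, 1, 2), fwd)
  if (nrow(pts) < 3L)
    stop("streamline terminated immediately (fewer than 3 points)")
  bt_curve(pts)
}
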