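#' SRAD filter settings
#'
#' @param dt Time step of the explicit diffusion update (stability requires
#'   \code{dt <= 0.25}).
#' @param n_iter Number of diffusion iterations.
#' @param h Grid spacing in pixels.
#' @param q0_region Homogeneous reference region used for the speckle scale:
#'   either \code{"auto"} (the 11x11 block of minimum variance in the input)
#'   or a rectangle \code{c(row0, col0, row1, col1)}.
#' @param eps Small positive guard added to intensities before division.
#' @param c_cap Finite upper clamp on the diffusion coefficient.
#' @export
srad_config <- function(dt = 0.05, n_iter = 100L, h = 1, q0_region = "auto",
                        eps = 1e-8, c_cap = 100) {
  stopifnot(dt > 0, dt <= 0.25, n_iter >= 1, h > 0, eps > 0, c_cap > 1)
  if (!(identical(q0_region, "auto") ||
        (is.numeric(q0_region) && length(q0_region) == 4L)))
    stop("q0_region must be \"auto\" or c(row0, col0, row1, col1)", call. = FALSE)
  structure(list(dt = dt, n_iter = as.integer(n_iter), h = h,
                 q0_region = q0_region, eps = eps, c_cap = c_cap),
            class = "srad_config")
}

#' Instantaneous coefficient of variation (ICOV)
#'
#' The normalized gradient/Laplacian edge detector driving SRAD:
#' \deqn{q = \sqrt{\max\left(0,
#'   \frac{(1/2)|\nabla I/I|^2 - (1/16)(\nabla^2 I/I)^2}
#'        {(1 + (1/4)\nabla^2 I/I)^2}\right)}}
#' with \eqn{|\nabla I|^2} the average of squared forward and backward
#' one-sided differences, the 4-neighbour Laplacian, and replicate
#' (zero-flux) boundaries.  High on edges, near zero on homogeneous regions.
#'
#' @param img Numeric image matrix (non-negative).
#' @param h Grid spacing in pixels.
#' @param eps Positive shift guarding division by zero intensities.
#' @return Matrix \code{q >= 0} of the same shape.
#' @export
icov <- function(img, h = 1, eps = 1e-8) {
  I <- img + eps
  dR <- ((sh_dn(I) - I)^2 + (sh_rt(I) - I)^2) / h^2   # forward differences
  dL <- ((I - sh_up(I))^2 + (I - sh_lf(I))^2) / h^2   # backward differences
  g2 <- 0.5 * (dR + dL)
  lap <- (sh_dn(I) + sh_up(I) + sh_rt(I) + sh_lf(I) - 4 * I) / h^2
  gi <- g2 / I^2
  li <- lap / I
  den <- (1 + 0.25 * li)^2
  den[den < eps] <- eps
  q2 <- (0.5 * gi - (1 / 16) * li^2) / den
  sqrt(pmax(q2, 0))
}

#' Speckle scale of a homogeneous region
#'
#' \code{q0 = sqrt(Var[Z]) / mean[Z]} (population variance) over a rectangular
#' region; for fully developed speckle with L looks this estimates
#' \code{1/sqrt(L)}.
#'
#' @param img Numeric image matrix.
#' @param region Rectangle \code{c(row0, col0, row1, col1)}, at least 4 pixels.
#' @export
speckle_scale <- function(img, region) {
  stopifnot(is.numeric(region), length(region) == 4L)
  r <- as.integer(region)
  if (r[1L] > r[3L] || r[2L] > r[4L] || r[1L] < 1L || r[2L] < 1L ||
      r[3L] > nrow(img) || r[4L] > ncol(img))
    stop("invalid region rectangle", call. = FALSE)
  v <- as.vector(img[r[1L]:r[3L], r[2L]:r[4L]])
  if (length(v) < 4L) stop("region must have at least 4 pixels", call. = FALSE)
  m <- mean(v)
  if (m == 0) stop("zero-mean region", call. = FALSE)
  sqrt(mean((v - m)^2)) / m
}

#' SRAD diffusion coefficient
#'
#' \code{C(q) = 1 / (1 + (q^2 - q0^2) / (q0^2 (1 + q0^2)))}, equal to 1 where
#' \code{q = q0}, tending to 0 for strong edges, and clamped to
#' \code{(0, c_cap]}.  A zero speckle scale gives no reliable estimate and
#' returns all ones (logged).
#'
#' @param q ICOV matrix (\code{q >= 0}).
#' @param q0 Speckle scale (scalar, \code{>= 0}).
#' @param c_cap Finite upper clamp.
#' @export
diffusion_coeff <- function(q, q0, c_cap = 100) {
  if (q0 < 0) stop("q0 must be non-negative", call. = FALSE)
  if (q0 == 0) {
    message("q0 = 0: no reliable speckle estimate, using C = 1 everywhere")
    return(matrix(1, nrow(q), ncol(q)))
  }
  C <- 1 / (1 + (q^2 - q0^2) / (q0^2 * (1 + q0^2)))
  pmin(pmax(C, .Machine$double.xmin), c_cap)
}

# 11x11 block of minimal intensity variance, as a rectangle
auto_q0_region <- function(img, s = 11L) {
  nr <- nrow(img) %/% s
  nc <- ncol(img) %/% s
  if (nr < 1L || nc < 1L)
    return(c(1L, 1L, nrow(img), ncol(img)))
  best <- NULL; best_v <- Inf
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rows <- ((r - 1L) * s + 1L):(r * s)
    cols <- ((c - 1L) * s + 1L):(c * s)
    v <- stats::var(as.vector(img[rows, cols]))
    if (v < best_v) { best_v <- v; best <- c(rows[1L], cols[1L], rows[s], cols[s]) }
  }
  best
}

#' Speckle-reducing anisotropic diffusion (SRAD)
#'
#' Iterative PDE despeckling: each iteration computes the ICOV edge map, the
#' speckle scale \code{q0} over the reference region (recomputed every
#' iteration from the evolving image), the diffusion coefficient, and an
#' explicit 4-neighbour divergence update
#' \code{I <- I + (dt/4) * div(C grad I)} with zero-flux boundaries.  Smooths
#' homogeneous speckle while preserving edges.
#'
#' @param img Numeric image matrix in \code{[0, 1]}.
#' @param cfg An \code{\link{srad_config}}.
#' @return Filtered image clipped to \code{[0, 1]}.
#' @export
srad_filter <- function(img, cfg = srad_config()) {
  assert_gray(img)
  reg <- if (identical(cfg$q0_region, "auto")) auto_q0_region(img) else as.integer(cfg$q0_region)
  I <- img
  q0_warned <- FALSE
  for (it in seq_len(cfg$n_iter)) {
    q <- icov(I, cfg$h, cfg$eps)
    q0 <- tryCatch(speckle_scale(I, reg), error = function(e) 0)
    if (q0 == 0) {
      if (!q0_warned) {
        message("q0 = 0 at iteration ", it, "; diffusing with C = 1")
        q0_warned <- TRUE
      }
      C <- matrix(1, nrow(I), ncol(I))
    } else {
      C <- suppressMessages(diffusion_coeff(q, q0, cfg$c_cap))
    }
    d <- sh_dn(C) * (sh_dn(I) - I) + C * (sh_up(I) - I) +
         sh_rt(C) * (sh_rt(I) - I) + C * (sh_lf(I) - I)
    I <- I + (cfg$dt / 4) * d
    if (anyNA(I) || any(!is.finite(I)))
      stop("SRAD diverged; reduce the time step dt", call. = FALSE)
  }
  clip01(I)
}
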