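#' Local mean filter
#'
#' Arithmetic mean over a \code{w x w} neighbourhood with reflective
#' (symmetric) border padding.
#'
#' @param img Numeric image matrix.
#' @param w Odd window size, at least 3.
#' @return Matrix of the same shape.
#' @export
local_mean <- function(img, w = 5L) {
  w <- as.integer(w)
  if (w %% 2L == 0L || w < 3L) stop("window size must be odd and >= 3", call. = FALSE)
  k <- (w - 1L) %/% 2L
  if (k >= nrow(img) || k >= ncol(img))
    stop("window too large for the image", call. = FALSE)
  p <- pad_reflect(img, k)
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(0, nr, nc)
  for (di in 0:(w - 1L))
    for (dj in 0:(w - 1L))
      acc <- acc + p[di + seq_len(nr), dj + seq_len(nc), drop = FALSE]
  acc / (w * w)
}

#' Neutrosophic T/I/F decomposition of an image
#'
#' Maps a gray image into the neutrosophic domain: the truth channel is the
#' range-normalized local mean, the indeterminacy channel is the
#' range-normalized absolute deviation from the local mean, and the falsity
#' channel is the complement of truth.
#'
#' @param img Numeric image matrix in \code{[0, 1]}.
#' @param w Local-mean window size (odd).
#' @return List with matrices \code{T_C}, \code{I_C}, \code{F_C},
#'   \code{local_mean} and \code{delta}.
#' @export
neutrosophic_components <- function(img, w = 5L) {
  assert_gray(img)
  q_hat <- local_mean(img, w)
  rng <- max(q_hat) - min(q_hat)
  if (rng == 0) stop("degenerate local-mean range (constant image)", call. = FALSE)
  T_C <- (q_hat - min(q_hat)) / rng
  delta <- abs(img - q_hat)
  drng <- max(delta) - min(delta)
  if (drng == 0) stop("degenerate deviation range (image equals its local mean)",
                      call. = FALSE)
  I_C <- (delta - min(delta)) / drng
  list(T_C = T_C, I_C = I_C, F_C = 1 - T_C, local_mean = q_hat, delta = delta)
}

#' Piecewise-quadratic S-function
#'
#' The sigmoid membership map with breakpoints \code{a < b < c}: 0 below
#' \code{a}, \code{(g-a)^2/((b-a)(c-a))} on \code{[a, b]},
#' \code{1 - (g-c)^2/((c-b)(c-a))} on \code{[b, c]}, and 1 above \code{c}.
#' Continuous (value \code{(b-a)/(c-a)}) at \code{g = b}.
#'
#' @param g Intensity value(s), any numeric array.
#' @param a,b,c Breakpoints with \code{a < b < c}, same units as \code{g}.
#' @export
s_function <- function(g, a, b, c) {
  if (!(a < b && b < c)) stop("require a < b < c", call. = FALSE)
  out <- ifelse(g <= a, 0,
         ifelse(g <= b, (g - a)^2 / ((b - a) * (c - a)),
         ifelse(g <= c, 1 - (g - c)^2 / ((c - b) * (c - a)), 1)))
  if (is.matrix(g)) out <- matrix(out, nrow(g), ncol(g))
  out
}

# plateau-aware local maxima of the 3-bin-smoothed histogram; a peak is a
# maximal run of equal smoothed values strictly above both adjacent runs,
# located at the raw-count maximum within the run.  Heights are raw counts.
find_histogram_peaks <- function(counts) {
  n <- length(counts)
  sm <- (c(0, counts[-n]) + counts + c(counts[-1], 0)) / 3
  r <- rle(sm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- integer(0)
  for (i in seq_along(r$values)) {
    left <- if (i == 1L) -Inf else r$values[i - 1L]
    right <- if (i == length(r$values)) -Inf else r$values[i + 1L]
    if (r$values[i] > left && r$values[i] > right) {
      run <- starts[i]:ends[i]
      peaks <- c(peaks, run[which.max(counts[run])])
    }
  }
  data.frame(level = peaks - 1L, height = counts[peaks])
}

#' Histogram-based estimation of the S-function breakpoints a and c
#'
#' From a 256-bin histogram of the image: local maxima are located, the peaks
#' whose heights exceed the mean peak height delimit the useful intensity
#' range (\code{g_min}, \code{g_max}); tail limits \code{B1}, \code{B2} allow
#' a fraction \code{f1} of pixels to be lost in each tail; \code{a} and
#' \code{c} are placed near the first/last local maxima and clamped to the
#' tail limits.  Levels are on the integer 0..255 scale.
#'
#' @param img Numeric image matrix in \code{[0, 1]}.
#' @param f1 Tail pixel-count fraction for the limits \code{B1}/\code{B2}.
#' @param f2 Interpolation fraction placing \code{a} and \code{c}.
#' @return List with \code{a}, \code{c}, \code{g_min}, \code{g_max},
#'   \code{B1}, \code{B2}, \code{g_1}, \code{g_n}, \code{peaks} (data frame),
#'   \code{peak_mean}.
#' @export
estimate_abc <- function(img, f1 = 0.01, f2 = 0.01) {
  assert_gray(img)
  stopifnot(f1 > 0, f1 < 1, f2 > 0, f2 < 1)
  lev <- as.integer(round(img * 255))
  counts <- tabulate(lev + 1L, nbins = 256L)
  peaks <- find_histogram_peaks(counts)
  peak_mean <- mean(peaks$height)
  qual <- peaks[peaks$height > peak_mean, , drop = FALSE]
  if (nrow(qual) < 2L)
    stop("fewer than 2 qualifying histogram peaks", call. = FALSE)
  g_min <- qual$level[1L]
  g_max <- qual$level[nrow(qual)]
  g_1 <- peaks$level[1L]
  g_n <- peaks$level[nrow(peaks)]
  n_pix <- length(lev)
  up <- cumsum(counts[(g_min + 1L):256L])             # counts from g_min upward
  B1 <- g_min + (which(up >= f1 * n_pix)[1L] - 1L)
  down <- cumsum(rev(counts[1L:(g_max + 1L)]))        # counts from g_max downward
  B2 <- g_max - (which(down >= f1 * n_pix)[1L] - 1L)
  a <- (1 - f2) * (g_1 - g_min) + g_min
  if (a > B1) a <- B1
  cc <- f2 * (g_max - g_n) + g_n
  if (cc > B2) cc <- B2
  list(a = a, c = cc, g_min = g_min, g_max = g_max, B1 = B1, B2 = B2,
       g_1 = g_1, g_n = g_n, peaks = peaks, peak_mean = peak_mean)
}

#' Mean binary entropy of a membership map
#'
#' \code{H = mean(Sn(T))} in bits, where \code{Sn} is the binary Shannon
#' entropy \code{-t log2 t - (1-t) log2 (1-t)} (with \code{0 log 0 = 0}).
#'
#' @param T Numeric array with values in \code{[0, 1]}.
#' @export
map_entropy <- function(T) {
  if (min(T) < 0 || max(T) > 1) stop("membership values must be in [0, 1]", call. = FALSE)
  t <- as.vector(T)
  sn <- numeric(length(t))
  ok <- t > 0 & t < 1
  tt <- t[ok]
  sn[ok] <- -tt * log2(tt) - (1 - tt) * log2(1 - tt)
  mean(sn)
}

#' Entropy-maximizing S-function midpoint
#'
#' Exhaustive scan of integer \code{b} in \code{[a+1, c-1]}: for each
#' candidate the image is mapped through \code{\link{s_function}} and the
#' \code{b} whose membership map has maximum \code{\link{map_entropy}} is
#' returned (ties break to the smallest \code{b}).
#'
#' @param img Numeric image matrix in \code{[0, 1]} (typically mean-filtered).
#' @param params List with breakpoints \code{a} and \code{c} on the 0..255
#'   level scale, e.g. from \code{\link{estimate_abc}}.
#' @return List with the winning \code{b}, its entropy \code{H} (bits) and the
#'   full \code{scan} data frame.
#' @export
optimal_b <- function(img, params) {
  assert_gray(img)
  bs <- seq.int(ceiling(params$a + 1), floor(params$c - 1))
  if (length(bs) < 1L || bs[1L] > bs[length(bs)])
    stop("empty search interval for b", call. = FALSE)
  g <- img * 255
  H <- vapply(bs, function(b) map_entropy(s_function(g, params$a, b, params$c)),
              numeric(1))
  i <- which.max(H)
  list(b = bs[i], H = H[i], scan = data.frame(b = bs, H = H))
}

#' Intensification transform
#'
#' Contrast intensifier on \code{[0, 1]}: \code{2T^2} below 0.5 and
#' \code{1 - 2(1-T)^2} above; monotone, fixing 0, 0.5 and 1.
#'
#' @param T Numeric array with values in \code{[0, 1]}.
#' @export
intensify <- function(T) {
  if (min(T) < 0 || max(T) > 1) stop("membership values must be in [0, 1]", call. = FALSE)
  out <- ifelse(T <= 0.5, 2 * T^2, 1 - 2 * (1 - T)^2)
  if (is.matrix(T)) out <- matrix(out, nrow(T), ncol(T))
  out
}

#' Unsharp-mask sharpening
#'
#' \code{clip(img + amount * (img - GaussianBlur(img, radius)), 0, 1)} with a
#' reflective-boundary Gaussian of standard deviation \code{radius}.
#'
#' @param img Numeric image matrix in \code{[0, 1]}.
#' @param radius Gaussian standard deviation in pixels.
#' @param amount Strength of the high-pass boost (0 = identity).
#' @export
unsharp_sharpen <- function(img, radius = 2, amount = 1) {
  assert_gray(img)
  stopifnot(radius > 0, amount >= 0)
  clip01(img + amount * (img - gaussian_blur(img, radius)))
}

#' Neutrosophic contrast enhancement
#'
#' The full enhancement stage: 5x5 mean filtering, histogram-based estimation
#' of the S-function breakpoints, entropy-maximizing choice of the midpoint
#' \code{b}, S-function mapping of the mean-filtered intensities,
#' intensification, and unsharp-mask sharpening.  When the histogram has too
#' few qualifying peaks the breakpoints fall back to the 1st/99th intensity
#' percentiles (logged via \code{message}); a constant image passes through
#' unchanged.
#'
#' @param img Numeric image matrix in \code{[0, 1]}.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param details If TRUE return a list with the enhanced \code{image} and the
#'   estimated \code{params}; otherwise just the image.
#' @export
enhance <- function(img, cfg = pipeline_config(), details = FALSE) {
  assert_gray(img)
  f <- local_mean(img, cfg$mean_filter_window)
  params <- tryCatch(estimate_abc(f, cfg$f1, cfg$f2), error = function(e) {
    message("breakpoint estimation failed (", conditionMessage(e),
            "); falling back to 1st/99th percentiles")
    q <- stats::quantile(f, c(0.01, 0.99), names = FALSE) * 255
    list(a = q[1L], c = q[2L], fallback = TRUE)
  })
  if (params$c - params$a < 2) {
    message("degenerate intensity range; image left unchanged")
    out <- img
    params$b <- NA_real_
  } else {
    ob <- optimal_b(f, params)
    params$b <- ob$b
    params$H <- ob$H
    T <- s_function(f * 255, params$a, params$b, params$c)
    out <- unsharp_sharpen(intensify(T), cfg$unsharp_radius, cfg$unsharp_amount)
  }
  if (details) list(image = out, params = params) else out
}
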