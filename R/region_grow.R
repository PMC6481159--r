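#' Seeded region growing with a constant intensity threshold
#'
#' Breadth-first growth from the seed pixel: the region mean is initialized to
#' the mean of the seed's \code{block_size x block_size} window (clipped to
#' the image); any untested neighbour of the region whose intensity differs
#' from the current mean by at most \code{tau} is admitted, and in
#' \code{"running"} mode the mean is updated to the running region mean after
#' every admission (\code{"frozen"} mode keeps the initial mean, which makes
#' growth a pure flood fill).  A pixel is tested at most once; the FIFO
#' frontier makes the result deterministic.  Interior holes of the final mask
#' are filled.
#'
#' @param img Numeric image matrix in \code{[0, 1]}.
#' @param seed Seed point: list or vector with \code{row} and \code{col}
#'   (1-based), e.g. from \code{\link{select_seed}}.
#' @param tau Constant admission threshold on the \code{[0, 1]} intensity
#'   scale (\code{>= 0}).
#' @param connectivity 4 or 8.
#' @param mean_mode \code{"running"} (classic seeded region growing, default)
#'   or \code{"frozen"}.
#' @param block_size Window size for the initial mean.
#' @param fill_holes Fill interior holes of the final mask.
#' @return List with \code{mask} (0/1 matrix), \code{size} (pixels before
#'   hole filling), \code{iterations} (pixels processed) and
#'   \code{region_mean}.
#' @export
region_growing <- function(img, seed, tau = 0.12, connectivity = 8L,
                           mean_mode = c("running", "frozen"),
                           block_size = 11L, fill_holes = TRUE) {
  assert_gray(img)
  mean_mode <- match.arg(mean_mode)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  if (is.list(seed)) {
    sr <- as.integer(seed$row); sc <- as.integer(seed$col)
  } else {
    sr <- as.integer(seed[1L]); sc <- as.integer(seed[2L])
  }
  H <- nrow(img); W <- ncol(img)
  if (sr < 1L || sr > H || sc < 1L || sc > W)
    stop("seed outside the image", call. = FALSE)
  k <- (as.integer(block_size) - 1L) %/% 2L
  win <- img[max(1L, sr - k):min(H, sr + k), max(1L, sc - k):min(W, sc + k)]
  mu <- mean(win)
  running <- mean_mode == "running"

  dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)[seq_len(connectivity)]
  dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)[seq_len(connectivity)]
  tested <- matrix(FALSE, H, W)
  member <- matrix(FALSE, H, W)
  queue <- integer(H * W)
  head <- 1L; tail <- 1L
  queue[tail] <- (sc - 1L) * H + sr; tail <- tail + 1L
  tested[sr, sc] <- TRUE; member[sr, sc] <- TRUE
  rsum <- img[sr, sc]; rn <- 1L
  iters <- 0L
  while (head < tail) {
    p <- queue[head]; head <- head + 1L
    iters <- iters + 1L
    pc <- (p - 1L) %/% H + 1L
    pr <- p - (pc - 1L) * H
    for (i in seq_along(dr)) {
      r <- pr + dr[i]; c <- pc + dc[i]
      if (r < 1L || r > H || c < 1L || c > W) next
      if (tested[r, c]) next
      tested[r, c] <- TRUE
      v <- img[r, c]
      if (abs(v - mu) <= tau) {
        member[r, c] <- TRUE
        rn <- rn + 1L; rsum <- rsum + v
        if (running) mu <- rsum / rn
        queue[tail] <- (c - 1L) * H + r; tail <- tail + 1L
      }
    }
  }
  size <- rn
  mask <- matrix(as.numeric(member), H, W)
  if (fill_holes)
    mask <- matrix(as.numeric(EBImage::fillHull(mask) > 0), H, W)
  list(mask = mask, size = size, iterations = iters, region_mean = rsum / rn)
}
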