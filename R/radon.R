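#' Partition an image into non-overlapping square blocks
#'
#' The image is tiled with \code{s x s} blocks starting at the top-left
#' corner; right/bottom remainders smaller than a block are dropped.  Blocks
#' are addressed by 1-based (row, column) grid positions or by the row-major
#' linear index \code{(r-1) * n_cols + c}.
#'
#' @param img Numeric image matrix, at least \code{s x s}.
#' @param s Block size in pixels.
#' @return An object of class \code{block_grid} with fields \code{s},
#'   \code{n_rows}, \code{n_cols}, \code{n_blocks} and the cropped
#'   \code{image}.
#' @export
partition_blocks <- function(img, s = 11L) {
  s <- as.integer(s)
  if (s < 3L) stop("block size must be >= 3", call. = FALSE)
  n_rows <- nrow(img) %/% s
  n_cols <- ncol(img) %/% s
  if (n_rows < 1L || n_cols < 1L)
    stop("image smaller than one block", call. = FALSE)
  structure(list(s = s, n_rows = n_rows, n_cols = n_cols,
                 n_blocks = n_rows * n_cols,
                 image = img[seq_len(n_rows * s), seq_len(n_cols * s),
                             drop = FALSE]),
            class = "block_grid")
}

#' Block grid indexing
#'
#' \code{block_index} maps a 1-based (row, column) grid position to the
#' row-major linear index \code{(r-1) * n_cols + c}; \code{block_position}
#' inverts it; \code{block_center} gives the image-pixel coordinates of a
#' block centre, \code{((r-1) s + (s+1)/2, (c-1) s + (s+1)/2)} (1-based).
#'
#' @param r,c Block row and column (1-based).
#' @param grid A \code{block_grid} (or any list with \code{n_rows},
#'   \code{n_cols}).
#' @param index Row-major linear block index.
#' @param s Odd block size in pixels.
#' @export
block_index <- function(r, c, grid) {
  if (any(r < 1L) || any(r > grid$n_rows) || any(c < 1L) || any(c > grid$n_cols))
    stop("block position outside the grid", call. = FALSE)
  (r - 1L) * grid$n_cols + c
}

#' @rdname block_index
#' @export
block_position <- function(index, grid) {
  if (any(index < 1L) || any(index > grid$n_rows * grid$n_cols))
    stop("block index outside the grid", call. = FALSE)
  r <- (index - 1L) %/% grid$n_cols + 1L
  c <- (index - 1L) %% grid$n_cols + 1L
  cbind(r = r, c = c)
}

#' @rdname block_index
#' @export
block_center <- function(r, c, s = 11L) {
  s <- as.integer(s)
  if (s %% 2L == 0L) stop("block size must be odd", call. = FALSE)
  cbind(row = (r - 1L) * s + (s + 1L) %/% 2L,
        col = (c - 1L) * s + (s + 1L) %/% 2L)
}

#' Extract one block's pixels
#'
#' @param grid A \code{block_grid}.
#' @param index Row-major linear block index.
#' @return The \code{s x s} intensity matrix of the block.
#' @export
get_block <- function(grid, index) {
  pos <- block_position(index, grid)
  s <- grid$s
  rows <- ((pos[1L, "r"] - 1L) * s + 1L):(pos[1L, "r"] * s)
  cols <- ((pos[1L, "c"] - 1L) * s + 1L):(pos[1L, "c"] * s)
  grid$image[rows, cols, drop = FALSE]
}

#' Radon projection of a square block
#'
#' Line-integral projection onto the axis at angle \code{theta}: each pixel's
#' value is splatted with bilinear weights onto the two offset bins nearest
#' \code{r = x cos(theta) + y sin(theta)} (pixel-centre coordinates relative
#' to the block centre, x along columns, y along rows).  This conserves the
#' total intensity exactly, reduces to per-column sums at \code{theta = 0}
#' and mirrors at \code{theta = 180}.  The projection has unit offset spacing
#' and odd length \code{>= ceiling(s * sqrt(2))}.
#'
#' @param block An \code{s x s} numeric matrix.
#' @param theta Projection angle in degrees, in \code{[0, 180]}.
#' @return List with \code{theta}, \code{samples} and \code{offsets}.
#' @export
radon_projection <- function(block, theta) {
  if (nrow(block) != ncol(block)) stop("block must be square", call. = FALSE)
  if (theta < 0 || theta > 180) stop("theta must be in [0, 180]", call. = FALSE)
  s <- nrow(block)
  P <- as.integer(ceiling(s * sqrt(2)))
  if (P %% 2L == 0L) P <- P + 1L
  m <- (P - 1L) %/% 2L
  th <- theta * pi / 180
  cc <- (s + 1) / 2
  x <- rep(seq_len(s) - cc, each = s)   # column offsets (column-major order)
  y <- rep(seq_len(s) - cc, times = s)  # row offsets
  r <- x * cos(th) + y * sin(th)
  v <- as.vector(block)
  f <- floor(r)
  t <- r - f
  idx <- c(f + m + 1, f + m + 2)
  wts <- c(v * (1 - t), v * t)
  keep <- wts != 0 & idx >= 1 & idx <= P
  samples <- numeric(P)
  if (any(keep)) {
    agg <- rowsum(wts[keep], group = idx[keep])
    samples[as.integer(rownames(agg))] <- agg[, 1L]
  }
  list(theta = theta, samples = samples, offsets = seq(-m, m))
}

#' Non-redundant bispectrum lattice
#'
#' Integer frequency pairs of the principal triangle
#' \code{0 <= k2 <= k1, k1 + k2 <= n_fft/2} (i.e. normalized frequencies
#' \code{0 <= f2 <= f1, f1 + f2 <= 1} with f = k/(n_fft/2), Nyquist = 1).
#'
#' @param n_fft FFT length (power of two).
#' @return Data frame with columns \code{k1}, \code{k2}.
#' @export
omega_lattice <- function(n_fft) {
  if (!is_pow2(n_fft)) stop("n_fft must be a power of two", call. = FALSE)
  half <- n_fft %/% 2L
  k1 <- integer(0); k2 <- integer(0)
  for (a in 0:half) {
    b <- 0:min(a, half - a)
    k1 <- c(k1, rep.int(a, length(b)))
    k2 <- c(k2, b)
  }
  data.frame(k1 = k1, k2 = k2)
}

#' Single-segment bispectrum of a projection
#'
#' The projection mean is subtracted (so the DC term does not dominate), the
#' signal zero-padded to \code{n_fft}, Fourier transformed, and the triple
#' product \code{B(k1, k2) = R(k1) R(k2) conj(R(k1 + k2))} evaluated on the
#' principal-triangle lattice of \code{\link{omega_lattice}}.
#'
#' @param proj A projection from \code{\link{radon_projection}}, or a numeric
#'   vector of samples.
#' @param n_fft FFT length: a power of two, at least the projection length.
#' @return List with \code{n_fft}, integer lattice \code{k1}, \code{k2}, and
#'   complex \code{values}.
#' @export
bispectrum <- function(proj, n_fft = 32L) {
  x <- if (is.list(proj)) proj$samples else proj
  n_fft <- as.integer(n_fft)
  if (!is_pow2(n_fft)) stop("n_fft must be a power of two", call. = FALSE)
  if (n_fft < length(x)) stop("n_fft shorter than the projection", call. = FALSE)
  xp <- c(x - mean(x), numeric(n_fft - length(x)))
  R <- stats::fft(xp)
  lat <- omega_lattice(n_fft)
  B <- R[lat$k1 + 1L] * R[lat$k2 + 1L] * Conj(R[lat$k1 + lat$k2 + 1L])
  list(n_fft = n_fft, k1 = lat$k1, k2 = lat$k2, values = B)
}

#' Bispectral entropies of one bispectrum estimate
#'
#' Four Shannon entropies (natural log) over the principal triangle:
#' \code{P1}, \code{P2}, \code{P3} from \code{|B|}, \code{|B|^2}, \code{|B|^3}
#' normalized to probability distributions, and the phase entropy \code{P_he}
#' from the histogram of \code{arg B} over \code{phase_bins} uniform bins on
#' \code{(-pi, pi]}.  An identically zero bispectrum yields all entropies 0.
#'
#' @param B A bispectrum estimate from \code{\link{bispectrum}}.
#' @param phase_bins Number of uniform phase-histogram bins.
#' @return List with \code{P_he}, \code{P1}, \code{P2}, \code{P3} (nats).
#' @export
bispectral_entropies <- function(B, phase_bins = 8L) {
  vals <- B$values
  if (length(vals) == 0L) stop("empty bispectrum", call. = FALSE)
  mag <- Mod(vals)
  s1 <- sum(mag)
  if (s1 == 0)
    return(list(P_he = 0, P1 = 0, P2 = 0, P3 = 0))
  P1 <- shannon(mag / s1)
  m2 <- mag^2; P2 <- shannon(m2 / sum(m2))
  m3 <- mag^3; P3 <- shannon(m3 / sum(m3))
  psi <- Arg(vals)
  bin <- pmin(pmax(ceiling((psi + pi) / (2 * pi) * phase_bins), 1L), phase_bins)
  p <- tabulate(bin, nbins = phase_bins) / length(psi)
  list(P_he = shannon(p), P1 = P1, P2 = P2, P3 = P3)
}

#' Per-block, per-angle bispectral entropy table
#'
#' For every block of the grid and every projection angle:
#' \code{\link{radon_projection}}, \code{\link{bispectrum}},
#' \code{\link{bispectral_entropies}}.  The feature matrix has one row per
#' block and \code{4 * length(angles)} columns ordered angle-major
#' (\code{P_he, P1, P2, P3} within each angle).
#'
#' @param grid A \code{block_grid}.
#' @param angles Projection angles in degrees.
#' @param n_fft FFT length for the bispectrum.
#' @param phase_bins Phase-histogram bins.
#' @return An object of class \code{entropy_table}: list with \code{features}
#'   (matrix), \code{feature_mean}, \code{feature_max} (per-column),
#'   \code{angles}, \code{table} (long-format data frame) and the grid
#'   dimensions.
#' @export
block_entropy_table <- function(grid, angles = c(0, 60, 120, 180),
                                n_fft = 32L, phase_bins = 8L) {
  stopifnot(inherits(grid, "block_grid"))
  nb <- grid$n_blocks
  na <- length(angles)
  feats <- matrix(0, nb, 4L * na)
  colnames(feats) <- as.vector(outer(c("P_he", "P1", "P2", "P3"), angles,
                                     function(f, a) paste0(f, "@", a)))
  long <- vector("list", nb * na)
  for (bi in seq_len(nb)) {
    blk <- get_block(grid, bi)
    pos <- block_position(bi, grid)
    for (ai in seq_len(na)) {
      pr <- radon_projection(blk, angles[ai])
      e <- bispectral_entropies(bispectrum(pr, n_fft), phase_bins)
      feats[bi, (ai - 1L) * 4L + 1:4] <- c(e$P_he, e$P1, e$P2, e$P3)
      long[[(bi - 1L) * na + ai]] <-
        data.frame(block = bi, row = pos[1L, "r"], col = pos[1L, "c"],
                   angle = angles[ai], P_he = e$P_he, P1 = e$P1,
                   P2 = e$P2, P3 = e$P3)
    }
  }
  structure(list(features = feats,
                 feature_mean = colMeans(feats),
                 feature_max = apply(feats, 2L, max),
                 angles = angles,
                 n_rows = grid$n_rows, n_cols = grid$n_cols,
                 table = do.call(rbind, long)),
            class = "entropy_table")
}
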