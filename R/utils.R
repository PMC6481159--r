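# internal numeric helpers shared across modules

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @noRd
assert_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (anyNA(img) || any(!is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  if (min(img) < 0 || max(img) > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  invisible(img)
}

# reflective ("abc|cba") padding by k pixels on every side
pad_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc)
    stop("padding exceeds image size", call. = FALSE)
  ri <- c(k:1, seq_len(nr), nr:(nr - k + 1))
  ci <- c(k:1, seq_len(nc), nc:(nc - k + 1))
  m[ri, ci, drop = FALSE]
}

# replicate-boundary one-pixel shifts (zero-flux at the borders)
sh_up <- function(m) m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE] # value of I[i-1, j]
sh_dn <- function(m) m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE] # I[i+1, j]
sh_lf <- function(m) m[, c(1L, seq_len(ncol(m) - 1L)), drop = FALSE] # I[i, j-1]
sh_rt <- function(m) m[, c(seq_len(ncol(m))[-1L], ncol(m)), drop = FALSE] # I[i, j+1]

# separable Gaussian blur, reflective boundary, kernel truncated at 3 sigma
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- as.integer(ceiling(3 * sigma))
  g <- stats::dnorm(-k:k, sd = sigma)
  g <- g / sum(g)
  p <- pad_reflect(img, k)
  nr <- nrow(img); nc <- ncol(img)
  tmp <- matrix(0, nr, nc + 2L * k)
  for (t in seq_along(g))
    tmp <- tmp + g[t] * p[(t - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (t in seq_along(g))
    out <- out + g[t] * tmp[, (t - 1L) + seq_len(nc), drop = FALSE]
  out
}

is_pow2 <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L

# Shannon entropy (natural log) of a probability vector; 0 log 0 = 0
shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
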