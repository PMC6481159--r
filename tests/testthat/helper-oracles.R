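# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: direct DFT sums, nested-loop filters, and
# dilation-based flood fill.

# O(n^2) discrete Fourier transform
dft_ref <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k)
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)), complex(1))
}

# brute-force triple-product bispectrum on the principal triangle
bispectrum_ref <- function(x, n_fft) {
  xp <- c(x - mean(x), numeric(n_fft - length(x)))
  R <- dft_ref(xp)
  half <- n_fft %/% 2
  out <- complex(0)
  for (k1 in 0:half) for (k2 in 0:min(k1, half - k1))
    out <- c(out, R[k1 + 1] * R[k2 + 1] * Conj(R[k1 + k2 + 1]))
  out
}

# nested-loop mean filter with reflective padding
local_mean_ref <- function(img, w) {
  k <- (w - 1) / 2
  H <- nrow(img); W <- ncol(img)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    acc <- 0
    for (dr in -k:k) for (dc in -k:k)
      acc <- acc + img[reflect(r + dr, H), reflect(c + dc, W)]
    out[r, c] <- acc / w^2
  }
  out
}

# single-window SSIM written out independently (population statistics)
ssim_ref <- function(A, B) {
  n <- length(A)
  muA <- sum(A) / n; muB <- sum(B) / n
  vA <- sum((A - muA)^2) / n
  vB <- sum((B - muB)^2) / n
  cAB <- sum((A - muA) * (B - muB)) / n
  C1 <- 1e-4; C2 <- 9e-4
  (2 * muA * muB + C1) * (2 * cAB + C2) /
    ((muA^2 + muB^2 + C1) * (vA + vB + C2))
}

# flood fill: connected component of {|I - mu| <= tau} containing the seed,
# grown by repeated dilation (no queues, independent of the BFS implementation)
flood_fill_ref <- function(img, seed_r, seed_c, mu, tau, connectivity = 8) {
  pass <- abs(img - mu) <= tau
  comp <- matrix(FALSE, nrow(img), ncol(img))
  comp[seed_r, seed_c] <- TRUE
  H <- nrow(img); W <- ncol(img)
  repeat {
    up <- rbind(FALSE, comp[-H, , drop = FALSE])
    dn <- rbind(comp[-1, , drop = FALSE], FALSE)
    lf <- cbind(FALSE, comp[, -W, drop = FALSE])
    rt <- cbind(comp[, -1, drop = FALSE], FALSE)
    grown <- up | dn | lf | rt
    if (connectivity == 8) {
      ul <- rbind(FALSE, cbind(FALSE, comp[-H, -W, drop = FALSE]))
      ur <- rbind(FALSE, cbind(comp[-H, -1, drop = FALSE], FALSE))
      dl <- rbind(cbind(FALSE, comp[-1, -W, drop = FALSE]), FALSE)
      dr <- rbind(cbind(comp[-1, -1, drop = FALSE], FALSE), FALSE)
      grown <- grown | ul | ur | dl | dr
    }
    new_comp <- comp | (grown & pass)
    if (identical(new_comp, comp)) break
    comp <- new_comp
  }
  matrix(as.numeric(comp), H, W)
}

# all-pairs directed-max Hausdorff on boundary coordinate sets
hausdorff_ref <- function(P, Q) {
  directed <- function(X, Y) {
    worst <- 0
    for (i in seq_len(nrow(X))) {
      best <- Inf
      for (j in seq_len(nrow(Y))) {
        d <- sqrt(sum((X[i, ] - Y[j, ])^2))
        if (d < best) best <- d
      }
      if (best > worst) worst <- best
    }
    worst
  }
  max(directed(P, Q), directed(Q, P))
}

# small speckled phantom for fast tests
tiny_phantom <- function(seed = 1, size = 66, a = 14, b = 10, looks = 4) {
  spec <- phantom_spec(size, size, background_level = 0.6,
                       lesions = data.frame(row = size / 2, col = size / 2,
                                            a = a, b = b, rot = 20,
                                            level = 0.2),
                       looks = looks, random_seed = seed)
  make_phantom(spec)
}

# preprocess a lesion phantom exactly as the pipeline does (enhance + SRAD)
# and return the mean P1 at 0 degrees over blocks fully inside the lesion
# together with the across-block mean
lesion_p1_check <- function(seed, size = 132) {
  spec <- phantom_spec(size, size,
                       lesions = data.frame(row = size / 2, col = size / 2,
                                            a = 26, b = 20, rot = 30,
                                            level = 0.2),
                       random_seed = seed)
  ph <- make_phantom(spec)
  des <- srad_filter(suppressMessages(enhance(ph$image)),
                     srad_config(n_iter = 100))
  g <- partition_blocks(des, 11)
  s <- 11
  inside <- vapply(seq_len(g$n_blocks), function(i) {
    p <- block_position(i, g)
    rows <- ((p[1, "r"] - 1) * s + 1):(p[1, "r"] * s)
    cols <- ((p[1, "c"] - 1) * s + 1):(p[1, "c"] * s)
    all(ph$mask[rows, cols] == 1)
  }, logical(1))
  p1 <- block_entropy_table(g)$features[, "P1@0"]
  list(lesion = mean(p1[inside]), overall = mean(p1))
}

# scene with structured (low-frequency) blocks and one near-constant block:
# the texture contrast the entropy features are built to detect
structured_scene <- function(seed = 4, nb = 5, s = 11, flat_block = c(3, 3)) {
  set.seed(seed)
  n <- nb * s
  img <- matrix(stats::runif(n * n, 0.3, 0.7), n, n)
  # heavy smoothing makes the texture low-frequency (structured)
  for (i in 1:3) img <- local_mean(img, 5)
  img <- 0.5 + (img - mean(img)) * 6          # restore contrast
  img <- pmin(pmax(img, 0), 1)
  rows <- ((flat_block[1] - 1) * s + 1):(flat_block[1] * s)
  cols <- ((flat_block[2] - 1) * s + 1):(flat_block[2] * s)
  img[rows, cols] <- 0.8 + stats::rnorm(s * s, sd = 0.003)
  pmin(pmax(img, 0), 1)
}
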