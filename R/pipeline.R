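#' Pipeline configuration
#'
#' All tunable parameters of the seed-selection and segmentation pipeline.
#' Defaults follow the method's stated settings: a 5x5 mean filter and tail
#' fractions f1 = f2 = 0.01 for the enhancement stage, 11x11 blocks,
#' projection angles 0/60/120/180 degrees, and 16 entropy features per block.
#'
#' @param mean_filter_window Odd mean-filter window (pixels).
#' @param f1,f2 Histogram tail fractions of the breakpoint estimator.
#' @param srad An \code{\link{srad_config}}.
#' @param block_size Odd block size s (pixels).
#' @param angles Radon projection angles (degrees).
#' @param fft_length Bispectrum FFT length: a power of two at least
#'   \code{ceiling(block_size * sqrt(2))}.
#' @param phase_bins Phase-histogram bins for the phase entropy.
#' @param region_grow_threshold Constant region-growing threshold on the
#'   \code{[0, 1]} intensity scale.
#' @param connectivity Region-growing connectivity, 4 or 8.
#' @param unsharp_radius,unsharp_amount Unsharp-mask parameters.
#' @param random_seed Optional integer seed recorded in the configuration
#'   (the pipeline itself is deterministic).
#' @export
pipeline_config <- function(mean_filter_window = 5L, f1 = 0.01, f2 = 0.01,
                            srad = srad_config(), block_size = 11L,
                            angles = c(0, 60, 120, 180), fft_length = 32L,
                            phase_bins = 8L, region_grow_threshold = 0.12,
                            connectivity = 8L, unsharp_radius = 2,
                            unsharp_amount = 1, random_seed = NULL) {
  mean_filter_window <- as.integer(mean_filter_window)
  block_size <- as.integer(block_size)
  fft_length <- as.integer(fft_length)
  stopifnot(mean_filter_window %% 2L == 1L, mean_filter_window >= 3L,
            f1 > 0, f1 < 1, f2 > 0, f2 < 1,
            block_size >= 3L, block_size %% 2L == 1L,
            phase_bins >= 2L,
            region_grow_threshold >= 0,
            connectivity %in% c(4L, 8L),
            unsharp_radius > 0, unsharp_amount >= 0,
            inherits(srad, "srad_config"))
  if (!is_pow2(fft_length) || fft_length < ceiling(block_size * sqrt(2)))
    stop("fft_length must be a power of two >= ceiling(block_size * sqrt(2))",
         call. = FALSE)
  if (any(angles < 0 | angles > 180))
    stop("angles must lie in [0, 180] degrees", call. = FALSE)
  structure(list(mean_filter_window = mean_filter_window, f1 = f1, f2 = f2,
                 srad = srad, block_size = block_size, angles = angles,
                 fft_length = fft_length, phase_bins = as.integer(phase_bins),
                 region_grow_threshold = region_grow_threshold,
                 connectivity = as.integer(connectivity),
                 unsharp_radius = unsharp_radius,
                 unsharp_amount = unsharp_amount,
                 random_seed = random_seed),
            class = "pipeline_config")
}

#' Run the full seed-selection and segmentation pipeline
#'
#' Applies, in order: neutrosophic enhancement and sharpening
#' (\code{\link{enhance}}), SRAD despeckling (\code{\link{srad_filter}}),
#' block partitioning and per-block bispectral entropies
#' (\code{\link{block_entropy_table}}), seed selection
#' (\code{\link{select_seed}}) and seeded region growing
#' (\code{\link{region_growing}}) on the despeckled image.  Fully
#' deterministic.
#'
#' @param img Numeric image matrix in \code{[0, 1]}, large enough for a
#'   2 x 2 grid of blocks.
#' @param cfg A \code{\link{pipeline_config}}.
#' @return List with \code{seed} (the \code{\link{select_seed}} result),
#'   \code{mask} (0/1 segmentation) and \code{diagnostics} (enhancement
#'   parameters, entropy table, candidates and SSIM sums, growth statistics,
#'   the enhanced and despeckled images).
#' @export
run_pipeline <- function(img, cfg = pipeline_config()) {
  assert_gray(img)
  if (nrow(img) < 2L * cfg$block_size || ncol(img) < 2L * cfg$block_size)
    stop("image too small: need at least a 2 x 2 grid of blocks", call. = FALSE)
  if (max(img) == min(img))
    stop("degenerate (constant) image", call. = FALSE)
  enh <- enhance(img, cfg, details = TRUE)
  des <- srad_filter(enh$image, cfg$srad)
  grid <- partition_blocks(des, cfg$block_size)
  tab <- block_entropy_table(grid, cfg$angles, cfg$fft_length, cfg$phase_bins)
  sel <- select_seed(tab, grid)
  grow <- region_growing(des, sel, cfg$region_grow_threshold,
                         cfg$connectivity, block_size = cfg$block_size)
  list(seed = sel, mask = grow$mask,
       diagnostics = list(enhance_params = enh$params,
                          entropy_table = tab,
                          candidates = sel$candidates,
                          ssim_sums = sel$ssim_sums,
                          grow = grow[c("size", "iterations", "region_mean")],
                          enhanced = enh$image, despeckled = des))
}

#' End-to-end benchmark on synthetic lesion phantoms
#'
#' For each seed: generates a 256x256 speckled phantom carrying one
#' elliptical hypoechoic lesion (background 0.6, lesion 0.2 -- contrast 0.4
#' -- speckle with \code{looks} looks; the lesion's centre, semi-axes and
#' orientation are drawn from the seed so every run sees a different
#' geometry), runs the full pipeline, and evaluates the selected seed point
#' and segmentation against the ground truth.
#'
#' @param seeds Integer RNG seeds, one phantom per seed.
#' @param size Phantom side length in pixels.
#' @param background,lesion_level Scene intensities.
#' @param looks Speckle looks L.
#' @param cfg A \code{\link{pipeline_config}}.
#' @param hd_mode Hausdorff aggregation mode.
#' @return Data frame with one row per phantom: \code{seed}, the selected
#'   seed point, \code{seed_in_lesion}, and TP/FP/DC/SI/HD.
#' @export
phantom_benchmark <- function(seeds = 1:20, size = 256L, background = 0.6,
                              lesion_level = 0.2, looks = 4,
                              cfg = pipeline_config(), hd_mode = "max") {
  res <- lapply(seeds, function(sd) {
    set.seed(sd)
    geom <- data.frame(row = round(stats::runif(1, size * 0.375, size * 0.625)),
                       col = round(stats::runif(1, size * 0.375, size * 0.625)),
                       a = stats::runif(1, 26, 36),
                       b = stats::runif(1, 20, 28),
                       rot = stats::runif(1, 0, 180),
                       level = lesion_level)
    spec <- phantom_spec(size, size, background, geom, looks = looks)
    ph <- make_phantom(spec)   # speckle continues the seeded RNG stream
    out <- run_pipeline(ph$image, cfg)
    ev <- evaluate_segmentation(out$mask, ph$mask, hd_mode)
    cbind(data.frame(seed = sd, seed_row = out$seed$row,
                     seed_col = out$seed$col,
                     seed_in_lesion = ph$mask[out$seed$row, out$seed$col] == 1),
          ev)
  })
  do.call(rbind, res)
}
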