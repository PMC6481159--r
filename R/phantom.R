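#' Specify a synthetic speckled ultrasound phantom
#'
#' A phantom is a flat echogenic background carrying one or more elliptical
#' homogeneous lesions (hypoechoic when \code{level < background_level}),
#' multiplied by fully developed speckle: per-pixel Gamma noise with shape
#' \code{looks} and mean 1, so the pixelwise expectation equals the noise-free
#' scene and the point signal-to-noise ratio in a flat region is
#' \code{sqrt(looks)}.
#'
#' @param height,width Image size in pixels.
#' @param background_level Background intensity in (0, 1].
#' @param lesions Data frame with one row per lesion and columns \code{row},
#'   \code{col} (centre, 1-based pixels), \code{a}, \code{b} (semi-axes,
#'   pixels), \code{rot} (rotation, degrees) and \code{level} (intensity).
#' @param looks Gamma shape parameter L of the multiplicative speckle
#'   (number of looks); larger is less noisy.
#' @param additive_sigma Standard deviation of optional additive Gaussian
#'   noise (0 disables it).
#' @param random_seed Integer seed; when non-NULL \code{make_phantom} seeds
#'   the RNG so the phantom is reproducible.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(height = 256L, width = 256L,
                         background_level = 0.6,
                         lesions = data.frame(row = 128, col = 128,
                                              a = 32, b = 24, rot = 0,
                                              level = 0.2),
                         looks = 4, additive_sigma = 0,
                         random_seed = NULL) {
  stopifnot(height >= 1, width >= 1,
            background_level > 0, background_level <= 1,
            looks > 0, additive_sigma >= 0)
  need <- c("row", "col", "a", "b", "rot", "level")
  if (!all(need %in% names(lesions)))
    stop("lesions needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(lesions$level == background_level))
    stop("lesion level must differ from the background level", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 background_level = background_level, lesions = lesions,
                 looks = looks, additive_sigma = additive_sigma,
                 random_seed = random_seed),
            class = "phantom_spec")
}

# pixel centres inside the rotated ellipse (centre-point rasterization)
ellipse_mask <- function(height, width, row0, col0, a, b, rot_deg) {
  th <- rot_deg * pi / 180
  y <- matrix(seq_len(height) - row0, height, width)
  x <- matrix(rep(seq_len(width) - col0, each = height), height, width)
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate a speckled phantom and its ground-truth lesion mask
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @return A list with elements \code{image} (speckled, clipped to
#'   \code{[0, 1]}), \code{mask} (0/1 union of the lesion ellipses) and
#'   \code{scene} (the noise-free image).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$random_seed)) set.seed(spec$random_seed)
  h <- spec$height; w <- spec$width
  scene <- matrix(spec$background_level, h, w)
  mask <- matrix(0, h, w)
  for (i in seq_len(nrow(spec$lesions))) {
    les <- spec$lesions[i, ]
    m <- ellipse_mask(h, w, les$row, les$col, les$a, les$b, les$rot)
    if (!any(m)) stop("lesion ", i, " rasterizes to zero pixels", call. = FALSE)
    if (any(m & mask == 1)) stop("lesions overlap", call. = FALSE)
    if (any(m[c(1L, h), ]) || any(m[, c(1L, w)]))
      stop("lesion ", i, " does not fit inside the image", call. = FALSE)
    scene[m] <- les$level
    mask[m] <- 1
  }
  img <- scene * matrix(stats::rgamma(h * w, shape = spec$looks,
                                      rate = spec$looks), h, w)
  if (spec$additive_sigma > 0)
    img <- img + matrix(stats::rnorm(h * w, sd = spec$additive_sigma), h, w)
  list(image = clip01(img), mask = mask, scene = scene)
}

#' Point signal-to-noise ratio inside a region
#'
#' Returns mean/standard-deviation (population sd) of the intensities inside
#' the region; for fully developed speckle with L looks this estimates
#' \code{sqrt(L)}.  A perfectly constant region returns \code{Inf}.
#'
#' @param img Numeric image matrix.
#' @param region 0/1 mask of the same shape selecting the region.
#' @export
speckle_snr <- function(img, region) {
  region <- validate_mask(region)
  if (!all(dim(img) == dim(region))) stop("shape mismatch", call. = FALSE)
  v <- img[region == 1]
  if (length(v) == 0L) stop("empty region", call. = FALSE)
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) return(Inf)
  mean(v) / s
}
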