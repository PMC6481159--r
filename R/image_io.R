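#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG, TIFF or PGM image as a numeric matrix with
#' intensities on the canonical \code{[0, 1]} scale (raw sample values divided
#' by \code{2^depth - 1}).  RGB inputs are converted to gray by averaging the
#' three colour channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG, TIFF or PGM (P2/P5) file.
#' @return A numeric matrix in \code{[0, 1]} (rows = image rows, row 1 at the
#'   top) with attribute \code{source_bit_depth}.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    depth <- read_png_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (length(frames) != 1L)
      stop("multi-frame TIFF not supported: ", path, call. = FALSE)
    a <- frames[[1L]]
    depth <- attr(a, "bits.per.sample")
    if (is.null(depth)) depth <- 8L
  } else if (ext == "pgm") {
    pgm <- read_pgm(path)
    a <- pgm$values
    depth <- pgm$depth
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3L]
    a <- if (nch >= 3L) (a[, , 1L] + a[, , 2L] + a[, , 3L]) / 3 else a[, , 1L]
  }
  img <- clip01(matrix(as.numeric(a), nrow(a), ncol(a)))
  attr(img, "source_bit_depth") <- as.integer(depth)
  img
}

# bit depth lives in byte 25 of the PNG stream (IHDR)
read_png_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 25L)
  if (length(hdr) < 25L) return(8L)
  as.integer(hdr[25L])
}

# minimal netpbm grayscale reader (ASCII P2 and binary P5)
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
      if (ch == "#") { # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) {
        out <- ch
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || grepl("[ \t\r\n]", ch)) return(out)
          out <- paste0(out, ch)
        }
      }
    }
  }
  magic <- tok()
  if (!magic %in% c("P2", "P5"))
    stop("not a PGM file (expected P2/P5): ", path, call. = FALSE)
  w <- as.integer(tok()); h <- as.integer(tok()); maxval <- as.integer(tok())
  if (anyNA(c(w, h, maxval)) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PGM header", call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    if (maxval < 256L) {
      v <- as.integer(readBin(con, "raw", n = n))
    } else {
      v <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                   endian = "big")
    }
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE, comment.char = "#")
  }
  if (length(v) < n) stop("truncated PGM pixel data", call. = FALSE)
  list(values = matrix(v / maxval, nrow = h, ncol = w, byrow = TRUE),
       depth = as.integer(round(log2(maxval + 1))))
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param path Output path (PNG).
#' @param img Numeric matrix in \code{[0, 1]}.
#' @export
write_gray_image <- function(path, img) {
  assert_gray(img)
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are stored as 8-bit PNG with foreground 255 and background 0; a write
#' followed by a read reproduces the mask exactly.
#'
#' @param path Path to a mask file.
#' @param mask 0/1 integer or numeric matrix.
#' @export
write_mask <- function(path, mask) {
  mask <- validate_mask(mask)
  png::writePNG(mask, target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- read_gray_image(path)
  m <- matrix(as.numeric(img > 0.5), nrow(img), ncol(img))
  m
}

#' @noRd
validate_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!all(mask %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  mask
}

#' Read a pipeline configuration file
#'
#' Configuration files are YAML with the same field names as
#' \code{\link{pipeline_config}}; SRAD settings go in a nested \code{srad}
#' block with the field names of \code{\link{srad_config}}.  Missing fields
#' keep their defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated \code{pipeline_config} object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  srad_args <- raw$srad
  raw$srad <- NULL
  srad <- if (is.null(srad_args)) srad_config() else do.call(srad_config, srad_args)
  if (!is.null(raw$angles)) raw$angles <- as.numeric(unlist(raw$angles))
  do.call(pipeline_config, c(raw, list(srad = srad)))
}
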