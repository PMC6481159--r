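#' Area-based segmentation metrics
#'
#' With \code{A} the automatically segmented set and \code{G} the ground
#' truth: \code{TP = 100 |A n G| / |A|}, \code{FP = 100 |A \\ G| / |A|}
#' (so TP + FP = 100 for non-empty A), Dice
#' \code{DC = 100 * 2|A n G| / (|A| + |G|)} and the similarity (Jaccard)
#' index \code{SI = 100 |A n G| / |A u G|}.  An empty automatic mask is
#' reported as TP 0 / FP 100 with a warning.
#'
#' @param auto,gt 0/1 mask matrices of identical shape; \code{gt} non-empty.
#' @return List with \code{TP}, \code{FP}, \code{DC}, \code{SI} (percent).
#' @export
area_metrics <- function(auto, gt) {
  auto <- validate_mask(auto); gt <- validate_mask(gt)
  if (!all(dim(auto) == dim(gt))) stop("mask shapes differ", call. = FALSE)
  nG <- sum(gt)
  if (nG == 0) stop("empty ground-truth mask", call. = FALSE)
  nA <- sum(auto)
  inter <- sum(auto * gt)
  if (nA == 0) {
    warning("empty automatic mask; TP/FP reported as 0/100")
    return(list(TP = 0, FP = 100, DC = 0, SI = 0))
  }
  list(TP = 100 * inter / nA,
       FP = 100 * (nA - inter) / nA,
       DC = 100 * 2 * inter / (nA + nG),
       SI = 100 * inter / (nA + nG - inter))
}

#' Boundary pixels of a mask
#'
#' A boundary pixel is a mask pixel with at least one background 4-neighbour;
#' pixels outside the image count as background, so mask pixels on the image
#' border are boundary pixels.
#'
#' @param mask 0/1 mask matrix.
#' @return 0/1 matrix marking the boundary.
#' @export
mask_boundary <- function(mask) {
  mask <- validate_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(0, mask[-H, , drop = FALSE])
  dn <- rbind(mask[-1L, , drop = FALSE], 0)
  lf <- cbind(0, mask[, -W, drop = FALSE])
  rt <- cbind(mask[, -1L, drop = FALSE], 0)
  matrix(as.numeric(mask == 1 & (up < 1 | dn < 1 | lf < 1 | rt < 1)), H, W)
}

# for each point of P (n x 2), the Euclidean distance to the nearest point of Q
nearest_distances <- function(P, Q, chunk = 512L) {
  n <- nrow(P)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- outer(P[i0:i1, 1L], Q[, 1L], "-")^2 +
          outer(P[i0:i1, 2L], Q[, 2L], "-")^2
    out[i0:i1] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Hausdorff distance between mask boundaries
#'
#' Symmetric Hausdorff distance (Euclidean, in pixels) between the boundary
#' pixel sets of the two masks: \code{max(h(dA, dG), h(dG, dA))} where the
#' directed term is the maximum (\code{mode = "max"}, classical) or the mean
#' (\code{mode = "mean"}, modified Hausdorff) of nearest-point distances.
#'
#' @param auto,gt Non-empty 0/1 mask matrices of identical shape.
#' @param mode \code{"max"} or \code{"mean"}.
#' @export
hausdorff_distance <- function(auto, gt, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  auto <- validate_mask(auto); gt <- validate_mask(gt)
  if (!all(dim(auto) == dim(gt))) stop("mask shapes differ", call. = FALSE)
  if (sum(auto) == 0 || sum(gt) == 0) stop("empty mask", call. = FALSE)
  bA <- which(mask_boundary(auto) == 1, arr.ind = TRUE)
  bG <- which(mask_boundary(gt) == 1, arr.ind = TRUE)
  dAG <- nearest_distances(bA, bG)
  dGA <- nearest_distances(bG, bA)
  agg <- if (mode == "max") max else mean
  max(agg(dAG), agg(dGA))
}

#' Full segmentation evaluation report
#'
#' @param auto,gt 0/1 mask matrices of identical shape.
#' @param hd_mode Hausdorff aggregation, see \code{\link{hausdorff_distance}}.
#' @return One-row data frame with columns TP, FP, DC, SI (percent) and HD
#'   (pixels).
#' @export
evaluate_segmentation <- function(auto, gt, hd_mode = "max") {
  am <- area_metrics(auto, gt)
  hd <- if (sum(auto) > 0) hausdorff_distance(auto, gt, hd_mode) else NA_real_
  data.frame(TP = am$TP, FP = am$FP, DC = am$DC, SI = am$SI, HD = hd)
}
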