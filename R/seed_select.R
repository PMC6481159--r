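#' Length of a block's qualifying entropy vector
#'
#' Counts the block's entropy features lying within the closed interval
#' between the across-block mean and maximum of that feature.
#'
#' @param features Numeric vector of one block's entropy features.
#' @param mean_f,max_f Per-feature across-block means and maxima.
#' @export
ev_length <- function(features, mean_f, max_f) {
  if (length(features) != length(mean_f) || length(features) != length(max_f))
    stop("feature vector and thresholds differ in length", call. = FALSE)
  sum(features >= mean_f & features <= max_f)
}

#' Candidate blocks with the longest entropy vector
#'
#' All block indices achieving the maximal \code{\link{ev_length}}, in
#' ascending order.
#'
#' @param table An \code{entropy_table}.
#' @export
candidate_blocks <- function(table) {
  stopifnot(inherits(table, "entropy_table"))
  L <- apply(table$features, 1L, ev_length,
             mean_f = table$feature_mean, max_f = table$feature_max)
  which(L == max(L))
}

#' Single-window SSIM between two blocks
#'
#' Structural similarity computed with one uniform window spanning the whole
#' block (population statistics), dynamic range \code{L = 1}, stabilizers
#' \code{C1 = (0.01 L)^2}, \code{C2 = (0.03 L)^2}:
#' \deqn{\mathrm{SSIM} = \frac{(2\mu_A\mu_B + C_1)(2\sigma_{AB} + C_2)}
#'   {(\mu_A^2 + \mu_B^2 + C_1)(\sigma_A^2 + \sigma_B^2 + C_2)}}
#'
#' @param A,B Numeric matrices of identical shape.
#' @return A similarity value in \code{[-1, 1]} (1 for identical blocks).
#' @export
block_ssim <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("blocks differ in shape", call. = FALSE)
  C1 <- 0.01^2
  C2 <- 0.03^2
  muA <- mean(A); muB <- mean(B)
  vA <- mean((A - muA)^2)
  vB <- mean((B - muB)^2)
  cAB <- mean((A - muA) * (B - muB))
  ((2 * muA * muB + C1) * (2 * cAB + C2)) /
    ((muA^2 + muB^2 + C1) * (vA + vB + C2))
}

#' Sum of SSIMs with the four grid neighbours
#'
#' Sums \code{\link{block_ssim}} between the block and its up/down/left/right
#' neighbours in the block grid; neighbours outside the grid contribute 0.
#'
#' @param grid A \code{block_grid}.
#' @param index Row-major linear block index.
#' @export
neighbor_ssim_sum <- function(grid, index) {
  pos <- block_position(index, grid)
  blk <- get_block(grid, index)
  total <- 0
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    r <- pos[1L, "r"] + d[1L]
    c <- pos[1L, "c"] + d[2L]
    if (r >= 1L && r <= grid$n_rows && c >= 1L && c <= grid$n_cols)
      total <- total + block_ssim(blk, get_block(grid, block_index(r, c, grid)))
  }
  total
}

#' Select the seed point
#'
#' Candidate blocks are those with the longest qualifying entropy vector; a
#' tie is broken in favour of the candidate with the largest 4-neighbour SSIM
#' sum, remaining ties by the lowest linear index.  The seed is the winning
#' block's centre pixel (1-based row, col).
#'
#' @param table An \code{entropy_table} for \code{grid}.
#' @param grid The \code{block_grid} the table was computed from.
#' @return List with \code{row}, \code{col}, \code{block} (winning index),
#'   \code{candidates} and (when a tie occurred) their \code{ssim_sums}.
#' @export
select_seed <- function(table, grid) {
  stopifnot(inherits(grid, "block_grid"))
  cand <- candidate_blocks(table)
  sums <- NULL
  if (length(cand) > 1L) {
    sums <- vapply(cand, function(i) neighbor_ssim_sum(grid, i), numeric(1))
    winner <- cand[sums == max(sums)][1L]
  } else {
    winner <- cand[1L]
  }
  pos <- block_position(winner, grid)
  ctr <- block_center(pos[1L, "r"], pos[1L, "c"], grid$s)
  list(row = ctr[1L, "row"], col = ctr[1L, "col"], block = winner,
       candidates = cand, ssim_sums = sums)
}
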