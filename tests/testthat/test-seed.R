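# constant-block SSIM is a closed form when variances vanish:
# SSIM(x, y) = (2xy + C1) / (x^2 + y^2 + C1); invert it for a target value
const_for_ssim <- function(x, s, C1 = 1e-4) {
  (x - sqrt(x^2 - s^2 * x^2 - s * (s - 1) * C1)) / s
}

test_that("entropy-vector length counts features between the across-block mean and max", {
  expect_equal(ev_length(rep(2, 16), rep(2, 16), rep(2, 16)), 16)

  # one feature over three blocks valued 1, 2, 3: mean 2, max 3
  mean_f <- 2; max_f <- 3
  expect_equal(sapply(1:3, ev_length, mean_f, max_f), c(0, 1, 1))

  expect_equal(ev_length(c(0.1, 0.2), c(0.5, 0.5), c(1, 1)), 0)
  expect_error(ev_length(1:3, 1:2, 1:2), "length")
})

test_that("candidate blocks are exactly the argmax set of the entropy-vector length", {
  fake_table <- function(features) {
    structure(list(features = features,
                   feature_mean = colMeans(features),
                   feature_max = apply(features, 2, max)),
              class = "entropy_table")
  }
  f <- matrix(0, 5, 2)
  f[4, ] <- c(5, 5)
  expect_equal(candidate_blocks(fake_table(f)), 4L)

  f2 <- matrix(1, 6, 3)  # all identical: everything ties
  expect_equal(candidate_blocks(fake_table(f2)), 1:6)

  f3 <- matrix(0, 5, 2); f3[2, 1] <- 9; f3[5, 2] <- 9
  expect_equal(candidate_blocks(fake_table(f3)), c(2L, 5L))
})

test_that("block SSIM is 1 on itself, matches the constant closed form and a reference implementation", {
  set.seed(19)
  A <- matrix(runif(121), 11, 11)
  expect_equal(block_ssim(A, A), 1)

  expect_equal(block_ssim(matrix(0, 11, 11), matrix(1, 11, 11)),
               1e-4 / (1 + 1e-4))

  for (i in 1:20) {
    B <- matrix(runif(121), 11, 11)
    expect_equal(block_ssim(A, B), ssim_ref(A, B), tolerance = 1e-9)
    A <- B
  }
  expect_error(block_ssim(A, matrix(0, 3, 3)), "shape")
})

test_that("neighbour SSIM sums count existing neighbours only", {
  g <- partition_blocks(matrix(0.5, 33, 33), 11)
  expect_equal(neighbor_ssim_sum(g, block_index(2, 2, g)), 4)  # interior
  expect_equal(neighbor_ssim_sum(g, 1L), 2)                    # corner
  expect_equal(neighbor_ssim_sum(g, 2L), 3)                    # edge
  expect_error(neighbor_ssim_sum(g, 99L), "outside")
})

test_that("the published tie is broken by the 4-neighbour SSIM sum toward block 187", {
  # 19 x 25 block grid (209 x 275 px); candidates 137 = (6,12) and 187 = (8,12).
  # Around 187 we plant constant blocks whose SSIMs with the constant-0.5
  # centre reproduce the published per-neighbour values.
  s <- 11
  img <- matrix(0.5, 19 * s, 25 * s)
  g <- partition_blocks(img, s)
  put <- function(r, c, v) {
    rows <- ((r - 1) * s + 1):(r * s); cols <- ((c - 1) * s + 1):(c * s)
    img[rows, cols] <<- v
  }
  targets <- c(0.443, 0.5748, 0.55709, 0.62586)
  nbrs <- list(c(7, 12), c(9, 12), c(8, 11), c(8, 13))
  for (i in 1:4) put(nbrs[[i]][1], nbrs[[i]][2], const_for_ssim(0.5, targets[i]))
  for (p in list(c(5, 12), c(6, 11), c(6, 13)))  # weak neighbours for 137
    put(p[1], p[2], 0.01)
  g <- partition_blocks(img, s)

  for (i in 1:4)
    expect_equal(block_ssim(get_block(g, block_index(8, 12, g)),
                            get_block(g, block_index(nbrs[[i]][1], nbrs[[i]][2], g))),
                 targets[i], tolerance = 1e-9)

  s187 <- neighbor_ssim_sum(g, 187L)
  expect_equal(s187, sum(targets), tolerance = 1e-8)   # = 2.20075, printed 2.2008
  expect_equal(s187, 2.2008, tolerance = 5e-5)
  s137 <- neighbor_ssim_sum(g, 137L)
  expect_lt(s137, s187)

  # entropy table making exactly {137, 187} the candidates
  feats <- matrix(0, g$n_blocks, 1)
  feats[c(137, 187), 1] <- 1
  tab <- structure(list(features = feats, feature_mean = colMeans(feats),
                        feature_max = apply(feats, 2, max)),
                   class = "entropy_table")
  expect_equal(candidate_blocks(tab), c(137L, 187L))
  sel <- select_seed(tab, g)
  expect_equal(sel$block, 187L)
  expect_equal(c(sel$row, sel$col), c(83L, 127L))
})

test_that("a single candidate yields its block centre directly", {
  img <- matrix(0.4, 18 * 11, 31 * 11)
  g <- partition_blocks(img, 11)
  feats <- matrix(0, g$n_blocks, 2)
  feats[block_index(8, 20, g), ] <- 3
  tab <- structure(list(features = feats, feature_mean = colMeans(feats),
                        feature_max = apply(feats, 2, max)),
                   class = "entropy_table")
  sel <- select_seed(tab, g)
  expect_equal(sel$block, 237L)
  expect_equal(c(sel$row, sel$col), c(83L, 215L))
})

test_that("an all-tie constant image deterministically selects the first interior block", {
  img <- matrix(0.5, 33, 33)
  g <- partition_blocks(img, 11)
  tab <- block_entropy_table(g, angles = c(0, 60, 120, 180))
  sel <- select_seed(tab, g)
  expect_equal(sel$candidates, 1:9)
  # all 9 blocks tie on entropy; the interior block has 4 unit-SSIM
  # neighbours (corners 2, edges 3), so the centre of the 3 x 3 grid wins
  expect_equal(sel$ssim_sums, c(2, 3, 2, 3, 4, 3, 2, 3, 2))
  expect_equal(sel$block, 5L)
  expect_equal(c(sel$row, sel$col), c(17L, 17L))
})

test_that("selection is invariant under an affine rescaling of one feature column", {
  scene <- structured_scene(seed = 20)
  g <- partition_blocks(scene, 11)
  tab <- block_entropy_table(g, angles = c(0, 60))
  sel1 <- select_seed(tab, g)
  tab2 <- tab
  tab2$features[, 3] <- 2.5 * tab2$features[, 3] + 0.7
  tab2$feature_mean <- colMeans(tab2$features)
  tab2$feature_max <- apply(tab2$features, 2, max)
  sel2 <- select_seed(tab2, g)
  expect_equal(sel2$block, sel1$block)
})

test_that("the seed always lies at a block centre inside the image", {
  set.seed(21)
  for (i in 1:5) {
    img <- matrix(runif(44 * 55), 44, 55)
    g <- partition_blocks(img, 11)
    tab <- block_entropy_table(g, angles = c(0, 90))
    sel <- select_seed(tab, g)
    expect_lte(sel$row, 44); expect_lte(sel$col, 55)
    pos <- block_position(sel$block, g)
    ctr <- block_center(pos[1, "r"], pos[1, "c"], 11)
    expect_equal(c(sel$row, sel$col), c(ctr[1, "row"], ctr[1, "col"]))
  }
})
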