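test_that("local mean matches a brute-force nested-loop filter", {
  expect_equal(local_mean(matrix(0.3, 6, 6), 5), matrix(0.3, 6, 6))

  z <- matrix(0, 5, 5); z[3, 3] <- 1
  expect_equal(local_mean(z, 3)[3, 3], 1 / 9)

  set.seed(2)
  img <- matrix(runif(49), 7, 7)
  expect_equal(local_mean(img, 3), local_mean_ref(img, 3), tolerance = 1e-12)
  expect_equal(local_mean(img, 5), local_mean_ref(img, 5), tolerance = 1e-12)

  expect_error(local_mean(img, 4), "odd")
})

test_that("neutrosophic components satisfy their normalization and complement identities", {
  set.seed(3)
  img <- matrix(runif(100), 10, 10)
  nc <- neutrosophic_components(img, 3)
  expect_equal(nc$F_C, 1 - nc$T_C)
  expect_equal(max(nc$T_C), 1)
  expect_equal(min(nc$T_C), 0)
  expect_true(all(nc$delta >= 0))
  expect_equal(nc$T_C[which.max(nc$local_mean)], 1)

  # brute-force check on a two-level step image
  step <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
  got <- neutrosophic_components(step, 3)
  q <- local_mean_ref(step, 3)
  expect_equal(got$T_C, (q - min(q)) / (max(q) - min(q)), tolerance = 1e-12)
  d <- abs(step - q)
  expect_equal(got$I_C, (d - min(d)) / (max(d) - min(d)), tolerance = 1e-12)

  expect_error(neutrosophic_components(matrix(0.5, 6, 6), 3), "degenerate")
})

test_that("S-function hits its branch endpoints, hand values, and is continuous and monotone", {
  expect_equal(s_function(10, 10, 50, 200), 0)
  expect_equal(s_function(200, 10, 50, 200), 1)
  expect_equal(s_function(128, 0, 128, 255), 128 / 255)
  expect_equal(s_function(-5, 10, 50, 200), 0)
  expect_equal(s_function(250, 10, 50, 200), 1)

  set.seed(4)
  for (i in 1:25) {
    abc <- sort(runif(3, 0, 255))
    if (abc[1] == abc[2] || abc[2] == abc[3]) next
    a <- abc[1]; b <- abc[2]; cc <- abc[3]
    left <- (b - a)^2 / ((b - a) * (cc - a))
    right <- 1 - (b - cc)^2 / ((cc - b) * (cc - a))
    expect_equal(left, right, tolerance = 1e-12)
    g <- sort(runif(50, a - 10, cc + 10))
    expect_true(all(diff(s_function(g, a, b, cc)) >= -1e-12))
  }
  expect_error(s_function(1, 5, 4, 10), "a < b < c")
})

test_that("breakpoint estimation reproduces the three-peak hand trace", {
  v <- c(rep(50, 300), rep(120, 80), rep(200, 280)) / 255
  img <- matrix(v, 20, 33)
  p <- estimate_abc(img, f1 = 0.01, f2 = 0.01)
  expect_equal(p$peaks$level, c(50, 120, 200))
  expect_equal(p$peaks$height, c(300, 80, 280))
  expect_equal(p$peak_mean, 220)
  expect_equal(p$g_min, 50)
  expect_equal(p$g_max, 200)
  expect_equal(p$a, 50)
  expect_equal(p$c, 200)
})

test_that("breakpoint estimation rejects unimodal histograms and keeps a < c <= g_max", {
  # deterministic smooth unimodal histogram: a single peak can never qualify
  counts <- round(400 * exp(-((0:255) - 128)^2 / (2 * 20^2)))
  v <- rep(0:255, counts) / 255
  pad <- (-length(v)) %% 100
  uni <- matrix(c(v, rep(128 / 255, pad)), ncol = 100)
  expect_error(estimate_abc(uni), "qualifying")

  for (i in 1:10) {
    centers <- sort(sample(30:220, 3))
    v <- c(rnorm(700, centers[1], 4), rnorm(700, centers[2], 4),
           rnorm(700, centers[3], 4)) / 255
    img <- matrix(pmin(pmax(v, 0), 1), 70, 30)
    p <- tryCatch(estimate_abc(img), error = function(e) NULL)
    if (is.null(p)) next
    expect_lt(p$a, p$c)
    expect_lte(p$c, p$g_max)
    expect_lte(p$a, p$B1)
  }
})

test_that("membership-map entropy is 1 bit at T = 0.5, 0 at the extremes, and symmetric", {
  expect_equal(map_entropy(matrix(0.5, 4, 4)), 1)
  expect_equal(map_entropy(matrix(c(0, 1), 4, 4)), 0)
  set.seed(6)
  T <- matrix(runif(64), 8, 8)
  expect_equal(map_entropy(T), map_entropy(1 - T), tolerance = 1e-12)
  expect_lt(map_entropy(matrix(0.3, 4, 4)), 1)
})

test_that("optimal b equals an independent exhaustive scan and stays inside (a, c)", {
  set.seed(7)
  img <- matrix(runif(32 * 32), 32, 32)
  res <- optimal_b(img, list(a = 20, c = 200))
  # independent scan
  H <- sapply(21:199, function(b) {
    T <- s_function(img * 255, 20, b, 200)
    t <- as.vector(T); t <- t[t > 0 & t < 1]
    sum(-t * log2(t) - (1 - t) * log2(1 - t)) / (32 * 32)
  })
  expect_equal(res$b, (21:199)[which.max(H)])
  expect_equal(res$H, max(H), tolerance = 1e-12)
  expect_gt(res$b, 20); expect_lt(res$b, 200)

  one <- optimal_b(img, list(a = 99, c = 101))
  expect_equal(one$b, 100)
  expect_error(optimal_b(img, list(a = 100, c = 101)), "empty")
})

test_that("intensification fixes 0, 0.5, 1 and evaluates its two branches", {
  expect_equal(intensify(c(0, 0.5, 1)), c(0, 0.5, 1))
  expect_equal(intensify(0.25), 0.125)
  expect_equal(intensify(0.75), 0.875)
  set.seed(8)
  t <- sort(runif(100))
  expect_true(all(diff(intensify(t)) >= 0))
})

test_that("unsharp masking is identity at amount 0, inert on constants, and local to edges", {
  set.seed(9)
  img <- matrix(runif(100), 10, 10)
  expect_equal(unsharp_sharpen(img, 2, 0), img)
  expect_equal(unsharp_sharpen(matrix(0.4, 12, 12), 2, 1.5), matrix(0.4, 12, 12))

  step <- cbind(matrix(0.2, 20, 15), matrix(0.8, 20, 15))
  out <- unsharp_sharpen(step, 2, 1)
  delta <- abs(out - step)
  # effect confined to within kernel reach (3 sigma) of the edge at col 15/16
  far <- delta[, c(1:8, 23:30)]
  expect_lt(max(far), 1e-9)
  expect_gt(max(delta), 0.05)
  edge_cols <- apply(delta, 2, max)
  expect_lte(abs(which.max(edge_cols) - 15.5), 2)
})

test_that("enhancement preserves rank order, passes constants through, and does not lose contrast", {
  cfg <- pipeline_config()
  # already-bimodal image (two coherent regions): separation must not decrease
  bim <- cbind(matrix(0.15, 60, 30), matrix(0.85, 60, 30))
  out <- suppressMessages(enhance(bim, cfg))
  lo <- mean(out[bim == 0.15]); hi <- mean(out[bim == 0.85])
  expect_gte(hi - lo, 0.85 - 0.15)

  cons <- matrix(0.4, 40, 40)
  expect_equal(suppressMessages(enhance(cons, cfg)), cons)

  ph <- tiny_phantom(seed = 2)
  enh <- suppressMessages(enhance(ph$image, cfg))
  raw_contrast <- abs(mean(ph$image[ph$mask == 1]) - mean(ph$image[ph$mask == 0]))
  enh_contrast <- abs(mean(enh[ph$mask == 1]) - mean(enh[ph$mask == 0]))
  expect_gte(enh_contrast, raw_contrast)
})
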