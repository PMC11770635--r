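test_that("iLumA% follows the strict-majority counting rule", {
  expect_equal(slide_iluma(rep(0.9, 8))$iluma_pct, 100)
  expect_identical(slide_iluma(rep(0.9, 8))$call, "pure")
  s <- slide_iluma(c(0.9, 0.8, 0.7, 0.2))
  expect_equal(s$iluma_pct, 75)
  expect_identical(s$call, "pure")
  # exactly half: admixed under strict majority
  tie <- slide_iluma(c(0.9, 0.9, 0.1, 0.1))
  expect_equal(tie$iluma_pct, 50)
  expect_identical(tie$call, "admixed")
  expect_error(slide_iluma(numeric(0)), "no patch")
})

test_that("iLumA% equals a brute-force count and ignores patch order", {
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    s <- slide_iluma(p)
    expect_equal(s$iluma_pct, 100 * sum(p > 0.5) / length(p))
    expect_gte(s$iluma_pct, 0); expect_lte(s$iluma_pct, 100)
    expect_equal(slide_iluma(sample(p))$iluma_pct, s$iluma_pct)
    expect_identical(s$call, if (s$iluma_pct > 50) "pure" else "admixed")
  }
})

test_that("patch classification is deterministic and order-preserving", {
  fx <- patch_training_data()
  tr <- suppressWarnings(train_classifier(fx$train$features, fx$train$labels,
                                          fx$val_pure,
                                          train_config(epochs = 3, seed = 1)))
  model <- select_model(tr)
  p1 <- classify_patches(model, fx$val_pure$features)
  p2 <- classify_patches(model, fx$val_pure$features)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  perm <- sample(length(p1))
  expect_identical(classify_patches(model,
                                    fx$val_pure$features[perm, , drop = FALSE]),
                   p1[perm])
  expect_error(classify_patches(model, fx$val_pure$features[, 1:5]),
               "input size")
  # trained model recognizes pure-LumA texture
  luma_rows <- fx$val_pure$labels == "LumA"
  expect_gt(mean(p1[luma_rows]), 0.5)
  expect_lt(mean(p1[!luma_rows]), 0.5)
})

grid_coords <- function(gh, gw, patch = 64L) {
  g <- expand.grid(row = (seq_len(gh) - 1L) * patch,
                   col = (seq_len(gw) - 1L) * patch)
  g[order(g$row, g$col), ]
}

test_that("a constant probability field is invariant under smoothing", {
  co <- grid_coords(6, 6)
  hm <- build_heatmap(co, rep(0.5, 36), c(384L, 384L), patch_size = 64L)
  expect_true(all(abs(hm$grid - 0.5) < 1e-12))
  expect_true(all(abs(hm$values - 0.5) < 1e-12, na.rm = TRUE))
  expect_identical(dim(hm$values), c(384L, 384L))
  expect_equal(hm$sigma, 2.5)
})

test_that("an isolated hot tile smooths to the kernel's central mass", {
  gh <- 21L; gw <- 21L
  co <- grid_coords(gh, gw)
  p <- rep(0, gh * gw)
  center <- which(co$row == 10 * 64 & co$col == 10 * 64)
  p[center] <- 1
  sigma <- 2.5
  hm <- build_heatmap(co, p, c(gh * 64L, gw * 64L), 64L, sigma = sigma)
  # direct double-loop convolution oracle
  r <- ceiling(3 * sigma)
  k1 <- dnorm(-r:r, sd = sigma)
  kern <- outer(k1, k1); kern <- kern / sum(kern)
  expect_equal(hm$grid[11, 11], kern[r + 1, r + 1], tolerance = 1e-12)
  # oracle over the full raster (image far from the boundary)
  oracle <- matrix(0, gh, gw)
  for (i in 1:gh) for (j in 1:gw) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- 11 + di; jj <- 11 + dj
      if (i == ii && j == jj) acc <- acc + kern[di + r + 1, dj + r + 1]
    }
    oracle[i, j] <- acc
  }
  expect_equal(hm$grid, oracle, tolerance = 1e-10)
})

test_that("smoothing preserves range and the mean of fully scored rasters", {
  set.seed(31)
  co <- grid_coords(8, 10)
  p <- runif(80)
  hm <- build_heatmap(co, p, c(512L, 640L), 64L, sigma = 1.7)
  expect_true(all(hm$grid >= 0 & hm$grid <= 1))
  expect_lt(abs(mean(hm$grid) - mean(p)), 1e-6)
})

test_that("unscored tiles stay missing and are excluded from smoothing", {
  co <- grid_coords(4, 4)[c(1, 2, 5, 6), ]   # top-left 2x2 block only
  hm <- build_heatmap(co, rep(1, 4), c(256L, 256L), 64L)
  expect_true(all(is.na(hm$grid[3:4, ])))
  expect_true(all(is.na(hm$grid[, 3:4])))
  # normalized convolution over the scored support keeps the value at 1
  expect_true(all(abs(hm$grid[1:2, 1:2] - 1) < 1e-12))
})

test_that("heatmap coordinates are validated", {
  co <- data.frame(row = c(0L, 64L), col = c(0L, 128L))
  expect_error(build_heatmap(co, c(0.5, 0.5), c(128L, 128L), 64L),
               "outside")
  expect_error(build_heatmap(data.frame(row = 10L, col = 0L), 0.5,
                             c(128L, 128L), 64L),
               "multiples")
})
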