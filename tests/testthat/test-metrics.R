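test_that("total area counts in-mask pixels", {
  expect_equal(total_area(matrix(TRUE, 100, 100)), 10000)
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  expect_equal(total_area(m), 1)
  set.seed(11)
  m2 <- matrix(runif(64 * 64) < 0.5, 64, 64)
  m2[1, 1] <- TRUE
  n <- 0
  for (i in 1:64) for (j in 1:64) if (m2[i, j]) n <- n + 1
  expect_equal(total_area(m2), n)
  expect_error(total_area(matrix(FALSE, 3, 3)), "empty")
})

test_that("area ratio is latent/known and may exceed 1", {
  full <- matrix(TRUE, 100, 100)
  expect_equal(area_ratio(full, full), 1.0)
  half <- matrix(FALSE, 100, 100); half[1:50, ] <- TRUE
  expect_equal(area_ratio(half, full), 0.5)
  m12 <- matrix(FALSE, 200, 100); m12[1:120, ] <- TRUE
  m10 <- matrix(FALSE, 200, 100); m10[1:100, ] <- TRUE
  expect_equal(area_ratio(m12, m10), 1.2)
})

test_that("intensity statistics are population mean and SD over the mask", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(intensity_stats(matrix(200, 10, 10), full),
               c(mean = 200, sd = 0))
  half <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  expect_equal(intensity_stats(half, full), c(mean = 127.5, sd = 127.5))
  set.seed(3)
  px <- matrix(sample(0:255, 25, replace = TRUE), 5, 5)
  msk <- matrix(runif(25) < 0.6, 5, 5); msk[1, 1] <- TRUE
  o <- oracle_intensity(px, msk)
  expect_equal(intensity_stats(px, msk), o[c("mean", "sd")])
})

test_that("deai is -(|mean - 127.5|), maximal at the midpoint", {
  full <- matrix(TRUE, 4, 4)
  expect_equal(deai(matrix(127.5, 4, 4), full), 0)
  expect_equal(deai(matrix(0, 4, 4), full), -127.5)
  expect_equal(deai(matrix(255, 4, 4), full), -127.5)
})

test_that("Michelson contrast follows (max-min)/(max+min)", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(michelson(matrix(80, 10, 10), full), 0)
  px <- matrix(sample(c(100, 150, 200), 100, replace = TRUE), 10, 10)
  px[1, 1] <- 200; px[2, 2] <- 100
  expect_equal(michelson(px, full), 100 / 300)
  expect_warning(z <- michelson(matrix(0, 4, 4), matrix(TRUE, 4, 4)),
                 "zero")
  expect_equal(z, 0)
})

test_that("block partition anchors at the mask bounding box with a 50% rule", {
  expect_length(block_partition(matrix(TRUE, 100, 100), 50), 4)
  # 60x60: one full tile; the three partial tiles are 20-50% covered -> out
  expect_length(block_partition(matrix(TRUE, 60, 60), 50), 1)
  # mask smaller than one tile but covering >= 50% of it
  m <- matrix(FALSE, 100, 100); m[10:49, 20:59] <- TRUE
  expect_length(block_partition(m, 50), 1)
  # a 30x30 mask covers 36% of a 50x50 tile -> nothing retained
  m2 <- matrix(FALSE, 100, 100); m2[1:30, 1:30] <- TRUE
  expect_error(block_partition(m2, 50), "coverage")
})

test_that("block intensity SD matches the explicit per-tile oracle", {
  full100 <- matrix(TRUE, 100, 100)
  expect_equal(block_intensity_sd(matrix(77, 100, 100), full100), 0)
  # exactly one all-black and one all-white tile
  m <- matrix(FALSE, 50, 100); m[, 1:100] <- TRUE
  px <- cbind(matrix(0, 50, 50), matrix(255, 50, 50))
  expect_equal(block_intensity_sd(px, m), sd(c(0, 255)))
  grad <- matrix(rep(seq(0, 255, length.out = 120), each = 120), 120, 120)
  o <- oracle_blocks(grad, matrix(TRUE, 120, 120), 50)
  expect_equal(block_intensity_sd(grad, matrix(TRUE, 120, 120)),
               sd(o$means))
})

test_that("block contrast separates global from local contrast", {
  full <- matrix(TRUE, 200, 200)
  px <- matrix(127, 200, 200)
  px[3, 3] <- 255; px[190, 190] <- 0
  expect_equal(michelson(px, full), 1)      # global sees the two pixels
  bc <- block_contrast(px, full)
  expect_lt(bc[["mean"]], 0.3)              # most blocks have 0 contrast
  checker <- matrix(ifelse((row(full) + col(full)) %% 2 == 0, 0, 255),
                    200, 200)
  bc2 <- block_contrast(checker, full)
  expect_equal(bc2[["mean"]], 1)
  expect_equal(bc2[["sd"]], 0)
  # synthetic smudge: one uniform tile among high-contrast tiles
  sm <- checker; sm[1:50, 1:50] <- 40
  full <- matrix(TRUE, 200, 200)
  o <- oracle_blocks(sm, full, 50)
  bc3 <- block_contrast(sm, full)
  expect_equal(bc3[["mean"]], mean(o$contrasts))
  expect_equal(bc3[["sd"]], sd(o$contrasts))
})

test_that("ridge sum is the Euclidean combination of two reliabilities", {
  expect_equal(ridge_sum(0, 0), 0)
  expect_equal(ridge_sum(1, 1), sqrt(2))
  expect_equal(ridge_sum(0.6, 0.8), 1.0)
  expect_error(ridge_sum(1.2, 0.5))
})

test_that("metrics equal brute-force oracles and respect their ranges on a
           randomized sweep", {
  for (seed in 1:200) {
    cs <- random_case(seed, max_side = 48)
    px <- cs$px; msk <- cs$mask
    o <- oracle_intensity(px, msk)
    expect_equal(intensity_stats(px, msk), o[c("mean", "sd")])
    expect_equal(deai(px, msk), -abs(o[["mean"]] - 127.5))
    expect_lte(deai(px, msk), 0)
    mich <- suppressWarnings(michelson(px, msk))
    expect_equal(mich, oracle_michelson(px, msk))
    expect_gte(mich, 0); expect_lte(mich, 1)
    bs <- c(10, 16, 25)[seed %% 3 + 1]
    ob <- oracle_blocks(px, msk, bs)
    if (length(ob$means) >= 2) {
      expect_equal(block_intensity_sd(px, msk, bs), sd(ob$means))
      bc <- block_contrast(px, msk, bs)
      expect_equal(bc[["mean"]], mean(ob$contrasts))
      expect_gte(bc[["mean"]], 0); expect_lte(bc[["mean"]], 1)
      # the global range dominates any block's range
      expect_gte(mich, max(ob$contrasts) - 1e-12)
    }
  }
})

test_that("metrics are invariant to translating the print in the canvas", {
  set.seed(99)
  px <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  msk <- matrix(runif(1600) < 0.7, 40, 40); msk[10:20, 10:20] <- TRUE
  canvas1 <- matrix(255, 120, 120); mask1 <- matrix(FALSE, 120, 120)
  canvas1[11:50, 11:50] <- px; mask1[11:50, 11:50] <- msk
  canvas2 <- matrix(255, 120, 120); mask2 <- matrix(FALSE, 120, 120)
  canvas2[61:100, 41:80] <- px; mask2[61:100, 41:80] <- msk
  expect_equal(intensity_stats(canvas1, mask1),
               intensity_stats(canvas2, mask2))
  expect_equal(michelson(canvas1, mask1), michelson(canvas2, mask2))
  expect_equal(block_intensity_sd(canvas1, mask1, 16),
               block_intensity_sd(canvas2, mask2, 16))
  expect_equal(block_contrast(canvas1, mask1, 16),
               block_contrast(canvas2, mask2, 16))
})
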