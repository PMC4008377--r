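test_that("generation is deterministic and classes carry their landmarks", {
  cfg <- gen_config(pattern = "whorl", seed = 42)
  a <- generate_known(cfg)
  b <- generate_known(cfg)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  expect_true(a$annotation$core_present)
  arch <- generate_known(gen_config(pattern = "arch", seed = 1))
  expect_false(arch$annotation$delta_present)
  expect_false(arch$annotation$core_present)
  expect_error(gen_config(pattern = "spiral"))
})

test_that("clean synthetic prints have highly reliable ridge flow", {
  for (p in c("whorl", "left-loop", "right-loop", "arch")) {
    k <- generate_known(gen_config(pattern = p, seed = 7))
    expect_gte(ridge_reliability(k$image, k$mask), 0.8)
    expect_true(all(k$image$pixels >= 0 & k$image$pixels <= 255))
  }
})

test_that("zero-strength degradation is the identity", {
  k <- generate_known(gen_config(pattern = "left-loop", seed = 5))
  l <- degrade_to_latent(k, degrade_config(crop_fraction = 1, n_smudges = 0,
                                           contrast_attenuation = 0,
                                           intensity_bias = 0, noise_sd = 0,
                                           seed = 3))
  expect_identical(l$mask, k$mask)
  expect_equal(l$image$pixels, k$image$pixels)
  expect_equal(l$image$role, "latent")
})

test_that("cropping scales total area as requested", {
  k <- generate_known(gen_config(pattern = "whorl", seed = 6))
  for (f in c(0.3, 0.5, 0.8)) {
    l <- degrade_to_latent(k, degrade_config(crop_fraction = f,
                                             n_smudges = 0, noise_sd = 0,
                                             contrast_attenuation = 0,
                                             seed = 11))
    expect_lt(abs(area_ratio(l$mask, k$mask) - f), 0.12)
  }
})

test_that("smudging monotonically erodes median ridge reliability", {
  med <- vapply(c(0, 4, 8), function(ns) {
    median(vapply(1:20, function(s) {
      k <- generate_known(gen_config(pattern = "whorl", seed = s))
      l <- degrade_to_latent(k, degrade_config(
        n_smudges = ns, crop_fraction = 1, contrast_attenuation = 0,
        noise_sd = 0, seed = s + 500))
      ridge_reliability(l$image, l$mask)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
  expect_lt(med[3], med[1])
})

test_that("panel simulation matches its closed-form accuracy anchors", {
  f0 <- data.frame(pair_id = sprintf("P%03d", 1:250),
                   is_match = rep(c(TRUE, FALSE), 125))
  cfg <- panel_config(beta0 = 0, beta = numeric(0), var_print = 0,
                      var_expert = 0, experts_per_batch = 20,
                      p_no_decision = 0, p_missing_ratings = 0, seed = 19)
  tr <- simulate_panel(f0, cfg)
  expect_equal(nrow(tr), 5000)
  expect_lt(abs(mean(tr$correct) - 0.5), 2 * sqrt(0.25 / 5000) * 2.6)

  cfg2 <- panel_config(beta0 = 3.385, beta = numeric(0), var_print = 0,
                       var_expert = 0, experts_per_batch = 20,
                       p_no_decision = 0, p_missing_ratings = 0, seed = 20)
  tr2 <- simulate_panel(f0, cfg2)
  p <- plogis(3.385)
  expect_lt(abs(mean(tr2$correct) - p), 2.6 * sqrt(p * (1 - p) / 5000) + 0.005)
})

test_that("generated difficulty and confidence are strongly anticorrelated", {
  raw <- simulate_raw_metrics(100, seed = 23)
  f <- assemble_features(raw)
  tr <- simulate_panel(f, panel_config(seed = 24))
  keep <- !is.na(tr$difficulty)
  expect_lt(cor(tr$difficulty[keep], tr$confidence[keep]), -0.6)
})

test_that("unstandardized features are rejected by the panel simulator", {
  raw <- simulate_raw_metrics(50, seed = 25)
  cfg <- panel_config(beta = c(ridge_sum = 0.419), seed = 1)
  expect_error(simulate_panel(raw, cfg), "standardized")
})

test_that("a study bundle has the designed size and balance", {
  b <- build_study(n_pairs = 200, with_images = FALSE, seed = 31)
  expect_equal(nrow(b$features), 200)
  expect_equal(sum(b$features$is_match), 100)
  expect_gte(nrow(b$raw_trials), 2000)
  expect_lte(nrow(b$raw_trials), 2400)
  b2 <- build_study(n_pairs = 200, with_images = FALSE, seed = 31)
  expect_identical(b$features, b2$features)
  expect_identical(b$trials, b2$trials)
  # metric range invariants hold on generated data
  expect_true(all(b$raw_metrics$deai_L <= 0))
  expect_true(all(b$raw_metrics$ridge_reliability_L >= 0 &
                    b$raw_metrics$ridge_reliability_L <= 1))
  expect_true(all(b$raw_metrics$michelson_L >= 0 &
                    b$raw_metrics$michelson_L <= 1))
})

test_that("an image-backed bundle runs the full metric chain", {
  b <- build_study(n_pairs = 12, with_images = TRUE, seed = 8,
                   panel = panel_config(experts_per_batch = 6,
                                        batch_size = 12))
  expect_equal(nrow(b$raw_metrics), 12)
  expect_true(all(b$raw_metrics$michelson_L <= 1))
  expect_true(all(b$raw_metrics$deai_K <= 0))
  expect_true(all(b$raw_metrics$total_area_L >= 1))
  expect_true(all(b$raw_metrics$ridge_reliability_K > 0.5))
  expect_gte(nrow(b$trials), 60)
})

test_that("smudge count drives simulated error rates through the features", {
  # 50-pair sweep: smudging is the only degradation that varies; errors
  # arise solely through the measured features entering the panel model
  n_sweep <- 50
  classes <- c("whorl", "left-loop", "right-loop", "arch")
  smudges <- rep(seq(0, 12, 2), length.out = n_sweep)
  rows <- vector("list", n_sweep)
  for (i in seq_len(n_sweep)) {
    k <- generate_known(gen_config(pattern = classes[(i - 1) %% 4 + 1],
                                   seed = 1000 + i))
    l <- degrade_to_latent(k, degrade_config(
      n_smudges = smudges[i], smudge_radius = 20, crop_fraction = 1,
      contrast_attenuation = 0.2, noise_sd = 4, seed = 2000 + i))
    rows[[i]] <- pair_metrics(l, k, k$annotation, k$annotation,
                              sprintf("P%03d", i), TRUE)
  }
  raw <- do.call(rbind, rows)
  f <- suppressWarnings(assemble_features(raw))
  tr <- simulate_panel(f, panel_config(
    beta0 = 2.5, beta = c(ridge_sum = 1.8, mean_block_contrast_L = 1.2),
    var_print = 0, var_expert = 0, experts_per_batch = 20,
    batch_size = 10, p_no_decision = 0, p_missing_ratings = 0, seed = 99))
  acc <- per_pair_accuracy(tr)$per_pair
  err <- 1 - acc$accuracy[match(sprintf("P%03d", seq_len(n_sweep)),
                                acc$pair_id)]
  expect_gt(cor(smudges, err, method = "spearman"), 0.5)
})
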