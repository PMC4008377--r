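test_that("with no random variation the crossed fit agrees with plain
           logistic regression", {
  sim <- simulate_crossed(150, 8, beta0 = 1.2, slopes = c(0.8, -0.6),
                          var_print = 0, var_expert = 0, seed = 21)
  fit <- fit_glmm(sim$data, "y", c("x1", "x2"))
  oracle <- glm(y ~ x1 + x2, binomial(), sim$data)
  ose <- summary(oracle)$coefficients[, 2]
  expect_lt(max(abs(fit$beta$estimate - coef(oracle)) / ose), 2)
  expect_lt(fit$var_print, 0.05)
  expect_lt(fit$var_expert, 0.05)
})

test_that("variance components near the generating values are recovered", {
  sim <- simulate_crossed(200, 12, beta0 = 3.4, slopes = -0.5,
                          var_print = 2.0, var_expert = 0, seed = 8)
  fit <- fit_glmm(sim$data, "y", "x1")
  expect_lt(abs(fit$beta$estimate[2] - (-0.5)), 2 * fit$beta$se[2])
  expect_gt(fit$var_print, 0.5)
  expect_true(is.finite(fit$aic))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$df)
})

test_that("a constant response raises a separation error", {
  sim <- simulate_crossed(20, 4, beta0 = 0, slopes = 0.1,
                          var_print = 0, var_expert = 0, seed = 2)
  sim$data$y <- 1
  expect_error(fit_glmm(sim$data, "y", "x1"), "separation|constant")
})

test_that("likelihood-ratio tests get chi2, df and p right", {
  set.seed(31)
  n <- 120
  x <- matrix(rnorm(n * 17), n, 17)
  colnames(x) <- paste0("x", 1:17)
  d <- data.frame(y = rbinom(n, 1, plogis(0.3 + 0.9 * x[, 1])), x)
  full <- fit_glmm(d, "y", paste0("x", 1:17), random = character(0))
  null <- fit_glmm(d, "y", character(0), random = character(0))
  res <- lrt(full, null)
  expect_equal(res$df, 17)
  expect_gte(res$chi2, 0)
  expect_equal(res$chi2, 2 * (full$loglik - null$loglik))
  same <- lrt(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  other <- fit_glmm(d, "y", "x2", random = character(0))
  expect_error(lrt(other, fit_glmm(d, "y", "x1", random = character(0))),
               "nested")
})

test_that("null-true likelihood ratios are approximately uniform", {
  pvals <- vapply(1:200, function(s) {
    set.seed(s + 4000)
    n <- 150
    d <- data.frame(y = rbinom(n, 1, 0.6), x1 = rnorm(n))
    full <- fit_glmm(d, "y", "x1", random = character(0))
    null <- fit_glmm(d, "y", character(0), random = character(0))
    lrt(full, null)$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("adding a fixed effect never lowers the log-likelihood", {
  for (s in 1:5) {
    sim <- simulate_crossed(60, 6, beta0 = 1, slopes = c(0.5, 0),
                            var_print = 0.5, var_expert = 0.2,
                            seed = s + 100)
    full <- fit_glmm(sim$data, "y", c("x1", "x2"))
    null <- fit_glmm(sim$data, "y", "x1")
    expect_gte(full$loglik, null$loglik - 1e-4)
  }
})

test_that("random-structure comparison reports the expertID test at 1 df", {
  sim <- simulate_crossed(80, 10, beta0 = 1.5, slopes = 0.6,
                          var_print = 1, var_expert = 1.0, seed = 55)
  res <- compare_random_structures(sim$data, "y", "x1", nAGQ = 0)
  expect_equal(res$lrt_expert$df, 1)
  expect_named(res$fits, c("both", "print_only", "expert_only"))
  expect_equal(nrow(res$expert_offsets), 10)
  expect_true(all(res$expert_offsets$se > 0))
})

test_that("zero-variance linear mixed fits match ordinary least squares", {
  set.seed(77)
  n_pairs <- 100; npe <- 6
  x <- rnorm(n_pairs)
  d <- expand.grid(pair = 1:n_pairs, expert = 1:npe)
  d$x1 <- x[d$pair]
  d$yy <- 2 + 0.7 * d$x1 + rnorm(nrow(d), 0, 0.5)
  d$pair_id <- factor(d$pair); d$expert_id <- factor(d$expert)
  fit <- fit_lmm(d, "yy", "x1")
  ols <- lm(yy ~ x1, d)
  ose <- summary(ols)$coefficients[, 2]
  expect_lt(max(abs(fit$beta$estimate - coef(ols)) / ose), 2)
})

test_that("difficulty and confidence models have opposite slope signs", {
  set.seed(13)
  n_pairs <- 120; npe <- 8
  x <- rnorm(n_pairs)
  d <- expand.grid(pair = 1:n_pairs, expert = 1:npe)
  d$x1 <- x[d$pair]
  d$difficulty <- 3.5 - 0.8 * d$x1 + rnorm(nrow(d), 0, 0.6)
  d$confidence <- 7 - d$difficulty + rnorm(nrow(d), 0, 0.4)
  d$pair_id <- factor(d$pair); d$expert_id <- factor(d$expert)
  fd <- fit_lmm(d, "difficulty", "x1")
  fc <- fit_lmm(d, "confidence", "x1")
  sd_ <- fd$beta$estimate[fd$beta$term == "x1"]
  sc_ <- fc$beta$estimate[fc$beta$term == "x1"]
  expect_lt(sd_ * sc_, 0)
  expect_lt(sd_, 0)
})

test_that("per-expert RT normalization centers each examiner", {
  set.seed(9)
  d <- data.frame(expert_id = rep(c("a", "b"), each = 50),
                  response_time = c(rlnorm(50, 3, 0.3), rlnorm(50, 4, 0.6)))
  z <- normalize_rt(d)
  for (e in c("a", "b")) {
    expect_lt(abs(mean(z[d$expert_id == e])), 1e-10)
    expect_equal(sd(z[d$expert_id == e]), 1)
  }
})

test_that("predicted accuracy is the inverse logit of the linear predictor", {
  fake <- structure(list(
    beta = data.frame(term = c("(Intercept)", "ridge_sum"),
                      estimate = c(3.385, 0.5), se = c(0.2, 0.1),
                      stat = c(17, 5)),
    fixed = "ridge_sum", family = "binomial",
    blups = list(pair_id = data.frame(level = "P1", offset = -1.5,
                                      se = 0.4))), class = "fp_glmm")
  f0 <- data.frame(pair_id = "P9", ridge_sum = 0)
  expect_equal(predict_accuracy(fake, f0), plogis(3.385))
  expect_equal(round(predict_accuracy(fake, f0), 3), 0.967)
  # linear predictor 0 -> 0.5
  fm <- data.frame(pair_id = "P9", ridge_sum = -3.385 / 0.5)
  expect_equal(predict_accuracy(fake, fm), 0.5)
  # monotone in a positive-coefficient feature
  grid <- data.frame(pair_id = "P9", ridge_sum = seq(-2, 2, 0.5))
  expect_true(all(diff(predict_accuracy(fake, grid)) > 0))
  # unseen pair gets the population prediction; seen pair gets its offset
  seen <- data.frame(pair_id = "P1", ridge_sum = 0)
  expect_equal(predict_accuracy(fake, seen, include_print_blup = TRUE),
               plogis(3.385 - 1.5))
  expect_equal(predict_accuracy(fake, f0, include_print_blup = TRUE),
               plogis(3.385))
  expect_error(predict_accuracy(fake, data.frame(pair_id = "x")), "ridge_sum")
})
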