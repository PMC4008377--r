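# End-to-end orchestration of the synthetic study analysis.

#' Derive a per-stage seed from a master seed
#'
#' A documented splitter so each pipeline stage is individually
#' reproducible: the master seed is mixed with a hash of the stage name by
#' integer arithmetic modulo 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character).
#' @return An integer in \[1, 2^31 - 2\].
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 69069 + h * 1009) %% 2147483646 + 1)
}

#' Run the full synthetic study analysis
#'
#' Simulate a study (images optional), screen features for collinearity,
#' fit the crossed logistic model of per-trial correctness, compare random
#' structures, reduce the fixed effects by AIC, evaluate per-pair predicted
#' vs observed accuracy (adjusted R^2, RMSE), run the stratified 90/10
#' validation with the threshold classifier, and fit the linear mixed
#' models for normalized response time, difficulty and confidence.
#' Deterministic given `seed`.
#'
#' @param n_pairs Number of print pairs.
#' @param seed Master seed.
#' @param with_images Render images (TRUE) or simulate metrics directly.
#' @param panel A [panel_config] describing the generating model.
#' @param test_fraction Held-out fraction for validation.
#' @param nAGQ Approximation order for logistic fits (0 = fast scans).
#' @return List of stage results; see the analysis scripts for usage.
#' @export
run_study <- function(n_pairs = 200, seed = 1, with_images = FALSE,
                      panel = panel_config(), test_fraction = 0.10,
                      nAGQ = 1) {
  bundle <- build_study(n_pairs = n_pairs, panel = panel,
                        with_images = with_images, seed = seed)
  screened <- collinearity_filter(bundle$features)
  feats <- screened$features
  mains <- attr(feats, "continuous_mains")
  inter <- paste0(attr(feats, "standardization")$interaction_bases, "_LxK")
  binary <- attr(feats, "binary")
  fixed <- c(mains, binary, inter)

  data <- merge(bundle$trials, feats, by = "pair_id")
  structures <- compare_random_structures(data, "correct", fixed,
                                          nAGQ = nAGQ)
  random <- if (structures$drop_expert) "pair_id" else
    c("pair_id", "expert_id")
  null_fit <- fit_glmm(data, "correct", character(0), random, nAGQ = nAGQ)
  selection <- aic_backward_select(data, "correct", fixed, random,
                                   nAGQ = nAGQ)
  fit <- selection$fit
  lrt_predictors <- lrt(fit, null_fit)

  obs <- per_pair_accuracy(bundle$trials)
  acc <- obs$per_pair$accuracy[match(feats$pair_id, obs$per_pair$pair_id)]
  # in-sample predicted proportions include the printID intercepts; unseen
  # pairs can only ever get the population-level prediction
  pred <- predict_accuracy(fit, feats, include_print_blup = TRUE)
  quality <- fit_quality(acc, pred, length(fit$fixed))
  quality_null <- fit_quality(acc, predict_accuracy(null_fit, feats), 0)

  split <- split_pairs(obs$per_pair$pair_id, obs$per_pair$perfect,
                       test_fraction, seed = stage_seed(seed, "split"))
  train_rows <- data[data$pair_id %in% split$train, ]
  train_fit <- fit_glmm(train_rows, "correct", fit$fixed, random,
                        nAGQ = nAGQ)
  idx_train <- feats$pair_id %in% split$train
  pred_train <- predict_accuracy(train_fit, feats[idx_train, ])
  pred_test <- predict_accuracy(train_fit, feats[!idx_train, ])
  perfect <- obs$per_pair$perfect[match(feats$pair_id,
                                        obs$per_pair$pair_id)]
  classifier <- optimize_threshold(pred_train, perfect[idx_train])
  test_result <- apply_classifier(classifier, pred_test,
                                  perfect[!idx_train])

  ratings <- data[!is.na(data$difficulty), ]
  ratings$norm_rt <- normalize_rt(ratings)
  lmm_fixed <- intersect(fixed, names(ratings))
  lmms <- list(
    response_time = fit_lmm(ratings, "norm_rt", lmm_fixed),
    difficulty = fit_lmm(ratings, "difficulty", lmm_fixed),
    confidence = fit_lmm(ratings, "confidence", lmm_fixed)
  )

  acc_test <- obs$per_pair$accuracy[
    match(feats$pair_id[!idx_train], obs$per_pair$pair_id)]
  quality_test <- fit_quality(acc_test, pred_test, length(fit$fixed))

  list(bundle = bundle, screen = screened$report, structures = structures,
       selection = selection, fit = fit, lrt_predictors = lrt_predictors,
       observed = obs, predicted = pred, quality = quality,
       quality_null = quality_null, quality_test = quality_test,
       split = split,
       train_fit = train_fit, classifier = classifier,
       test_result = test_result, lmms = lmms)
}
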