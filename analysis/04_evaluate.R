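#!/usr/bin/env Rscript

# Stage 4: model assessment and validation.
#
# Per-pair observed vs predicted accuracy (adjusted R^2 and RMSE against the
# intercept-only null), a stratified 90/10 train/test split, the
# predicted-accuracy threshold classifier trained on the training pairs and
# applied to the held-out pairs, and the difficulty-augmented model. Writes
# results/evaluation.json, the per-pair table, and a predicted-vs-observed
# scatter plot.

library(printdiff)

study <- "results/study"
features <- read.csv(file.path(study, "features.csv"))
trials <- suppressMessages(read_trials(file.path(study, "trials_clean.csv")))
model <- jsonlite::read_json("results/accuracy_model.json",
                             simplifyVector = TRUE)
fixed <- model$selected
data <- merge(trials, features, by = "pair_id")
random <- if (model$drop_expert) "pair_id" else c("pair_id", "expert_id")

fit <- fit_glmm(data, "correct", fixed, random)
null_fit <- fit_glmm(data, "correct", character(0), random)

obs <- per_pair_accuracy(trials)
acc <- obs$per_pair$accuracy[match(features$pair_id, obs$per_pair$pair_id)]
pred <- predict_accuracy(fit, features, include_print_blup = TRUE)
quality <- fit_quality(acc, pred, length(fixed))
quality_null <- fit_quality(acc, predict_accuracy(null_fit, features), 0)
message(sprintf("in-sample: R2_adj = %.2f, RMSE = %.3f (null RMSE = %.3f)",
                quality$r2_adj, quality$rmse, quality_null$rmse))

split <- split_pairs(obs$per_pair$pair_id, obs$per_pair$perfect, 0.10,
                     seed = 20260920)
idx_tr <- features$pair_id %in% split$train
fit_tr <- fit_glmm(data[data$pair_id %in% split$train, ], "correct", fixed,
                   random)
pred_tr <- predict_accuracy(fit_tr, features[idx_tr, ])
pred_te <- predict_accuracy(fit_tr, features[!idx_tr, ])
perfect <- obs$per_pair$perfect[match(features$pair_id,
                                      obs$per_pair$pair_id)]
classifier <- optimize_threshold(pred_tr, perfect[idx_tr])
held_out <- apply_classifier(classifier, pred_te, perfect[!idx_tr])
baseline_tr <- mean(perfect[idx_tr])
message(sprintf(
  "classifier: threshold %.3f, train %.0f%% (naive %.0f%%), test %.0f%%",
  classifier$threshold, 100 * classifier$accuracy, 100 * baseline_tr,
  100 * held_out$accuracy))

# difficulty augmentation requires rated trials; refit the base model on
# the rated subset so the likelihood-ratio test compares like with like
rated <- data[!is.na(data$difficulty), ]
fit_rated <- fit_glmm(rated, "correct", fixed, random)
aug <- augment_with_difficulty(rated, fit_rated)
message(sprintf("difficulty-augmented model: chi2(%d) = %.1f, p = %.2g",
                aug$lrt$df, aug$lrt$chi2, aug$lrt$p))

per_pair <- data.frame(pair_id = features$pair_id, observed = acc,
                       predicted = pred, perfect = perfect,
                       test_set = !idx_tr)
write.csv(per_pair, "results/per_pair_predictions.csv", row.names = FALSE)
writeLines(jsonlite::toJSON(list(
  overall_accuracy = obs$overall, match_accuracy = obs$match_accuracy,
  nonmatch_accuracy = obs$nonmatch_accuracy, n_perfect = obs$n_perfect,
  r2_adj = quality$r2_adj, rmse = quality$rmse,
  rmse_null = quality_null$rmse,
  threshold = classifier$threshold, train_accuracy = classifier$accuracy,
  train_baseline = baseline_tr, test_accuracy = held_out$accuracy,
  confusion_test = as.data.frame(as.table(held_out$confusion)),
  difficulty_lrt = aug$lrt), auto_unbox = TRUE, pretty = TRUE, digits = NA),
  "results/evaluation.json")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  p <- ggplot(per_pair, aes(predicted, observed, colour = test_set)) +
    geom_abline(linetype = 2, colour = "grey60") +
    geom_point(alpha = 0.8) +
    coord_equal(xlim = 0:1, ylim = 0:1) +
    labs(x = "Predicted accuracy", y = "Observed accuracy",
         colour = "Held out") +
    theme_minimal()
  ggsave("results/predicted_vs_observed.png", p, width = 5, height = 4,
         dpi = 150)
}
message("wrote results/evaluation.json")
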