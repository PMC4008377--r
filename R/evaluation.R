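# Model assessment: per-pair observed vs predicted accuracy, adjusted R^2
# and RMSE, the stratified 90/10 validation split, and the perfect /
# non-perfect threshold classifier.

#' Observed accuracy per print pair
#'
#' Fraction of correct judgments per pair across the experts who saw it,
#' plus global summaries: mean per-pair accuracy overall and by match
#' status, and the number of "perfect" pairs (observed accuracy exactly 1
#' across that pair's trials).
#'
#' @param trials Trial data.frame with `pair_id`, `is_match`, `correct`.
#' @return List: `per_pair` (pair_id, is_match, n_trials, n_correct,
#'   accuracy, perfect), `overall`, `match_accuracy`, `nonmatch_accuracy`,
#'   `n_perfect`.
#' @export
per_pair_accuracy <- function(trials) {
  agg <- stats::aggregate(correct ~ pair_id + is_match, data = trials,
                          FUN = function(x) c(n = length(x), k = sum(x)))
  per_pair <- data.frame(pair_id = agg$pair_id, is_match = agg$is_match,
                         n_trials = agg$correct[, "n"],
                         n_correct = agg$correct[, "k"])
  per_pair$accuracy <- per_pair$n_correct / per_pair$n_trials
  per_pair$perfect <- per_pair$accuracy == 1
  per_pair <- per_pair[order(per_pair$pair_id), , drop = FALSE]
  rownames(per_pair) <- NULL
  list(per_pair = per_pair,
       overall = mean(per_pair$accuracy),
       match_accuracy = mean(per_pair$accuracy[per_pair$is_match]),
       nonmatch_accuracy = mean(per_pair$accuracy[!per_pair$is_match]),
       n_perfect = sum(per_pair$perfect))
}

#' Goodness of fit of predicted to observed per-pair accuracy
#'
#' `R^2 = 1 - SSE/SST` of the predictions against the observed per-pair
#' accuracies, adjusted as `1 - (1 - R^2)(n - 1)/(n - k - 1)` with `k`
#' fixed-effect predictors; RMSE is the root mean squared
#' predicted-observed difference.
#'
#' @param observed,predicted Per-pair accuracies and predicted
#'   probabilities, equal length.
#' @param n_predictors Number of fixed-effect predictors `k`.
#' @return List with `r2`, `r2_adj`, `rmse`, `n`.
#' @export
fit_quality <- function(observed, predicted, n_predictors) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n < n_predictors + 2) stop("need at least n_predictors + 2 pairs")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst < 1e-24) {
    warning("observed accuracies have no variance; R^2 undefined")
    r2 <- r2_adj <- NA_real_
  } else {
    r2 <- 1 - sse / sst
    r2_adj <- 1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
  }
  list(r2 = r2, r2_adj = r2_adj, rmse = sqrt(sse / n), n = n)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Stratified train/test split of print pairs
#'
#' Samples `test_fraction` of the pairs into a held-out set, stratified on
#' perfect vs non-perfect observed accuracy so the test set preserves the
#' population mix. Deterministic under `seed`.
#'
#' @param pair_ids Vector of pair identifiers.
#' @param perfect Logical vector: was the pair judged correctly by every
#'   expert?
#' @param test_fraction Held-out fraction (default 0.10).
#' @param seed Integer RNG seed.
#' @return List with `train` and `test` (vectors of pair ids).
#' @export
split_pairs <- function(pair_ids, perfect, test_fraction = 0.10, seed = 1) {
  stopifnot(length(pair_ids) == length(perfect))
  strata <- split(pair_ids, perfect)
  if (length(strata) < 2L) stop("both perfect and non-perfect strata must be nonempty")
  test <- with_seed(seed, {
    unlist(lapply(strata, function(ids) {
      k <- round(test_fraction * length(ids))
      if (k < 1 || k >= length(ids)) {
        stop("stratum too small for a ", test_fraction, " test fraction")
      }
      sample(ids, k)
    }), use.names = FALSE)
  })
  list(train = setdiff(pair_ids, test), test = test)
}

confusion_counts <- function(predicted_perfect, perfect) {
  matrix(c(sum(perfect & predicted_perfect),
           sum(perfect & !predicted_perfect),
           sum(!perfect & predicted_perfect),
           sum(!perfect & !predicted_perfect)),
         nrow = 2, byrow = TRUE,
         dimnames = list(actual = c("perfect", "non_perfect"),
                         predicted = c("perfect", "non_perfect")))
}

classifier_result <- function(threshold, predicted, perfect) {
  cm <- confusion_counts(predicted >= threshold, perfect)
  structure(list(threshold = threshold, confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm), n = sum(cm)),
            class = "fp_classifier")
}

#' @export
print.fp_classifier <- function(x, ...) {
  cat(sprintf("<classifier: threshold %.4f, accuracy %d/%d = %.1f%%>\n",
              x$threshold, sum(diag(x$confusion)), x$n, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Choose the predicted-accuracy threshold that best separates perfect pairs
#'
#' Pairs with predicted accuracy at or above the threshold are classified
#' as perfect (no expert expected to err). The sweep visits every observed
#' predicted value plus 0 and 1 and returns the training-accuracy maximizer;
#' ties go to the highest threshold, the conservative choice that flags more
#' pairs as potentially error-prone.
#'
#' @param predicted Predicted accuracies on the training pairs.
#' @param perfect Logical training labels.
#' @return An `fp_classifier`: `threshold`, `confusion`, `accuracy`, `n`.
#' @export
optimize_threshold <- function(predicted, perfect) {
  if (length(unique(perfect)) < 2L) {
    stop("both classes must be present to optimize a threshold")
  }
  thresholds <- sort(unique(c(0, predicted, 1)))
  acc <- vapply(thresholds, function(t) {
    mean((predicted >= t) == perfect)
  }, numeric(1))
  best <- max(which(acc == max(acc)))   # tie -> highest threshold
  classifier_result(thresholds[best], predicted, perfect)
}

#' Apply a trained threshold to held-out pairs
#'
#' @param classifier An `fp_classifier` from [optimize_threshold] (or a bare
#'   numeric threshold).
#' @param predicted Predicted accuracies for held-out pairs.
#' @param perfect Logical held-out labels.
#' @return An `fp_classifier` evaluated on the held-out pairs.
#' @export
apply_classifier <- function(classifier, predicted, perfect) {
  threshold <- if (inherits(classifier, "fp_classifier"))
    classifier$threshold else classifier
  classifier_result(threshold, predicted, perfect)
}

#' Add mean per-pair difficulty rating as a predictor and refit
#'
#' Difficulty ratings are subjective -- they vary across examiners and rely
#' on good-faith reporting -- so the augmented model is reported alongside,
#' not instead of, the purely image-based one. The per-pair mean rating is
#' z-scored across pairs before entering the model.
#'
#' @param data Trial rows joined to features (must include `difficulty`).
#' @param fit The image-only `fp_glmm` to augment (same data rows).
#' @return List: `fit` (augmented), `base` (original), `lrt` comparing
#'   them, and `note` flagging the subjectivity caveat.
#' @export
augment_with_difficulty <- function(data, fit) {
  if (!"difficulty" %in% names(data)) stop("difficulty ratings are missing")
  if (anyNA(data$difficulty)) stop("difficulty ratings contain missing values")
  mean_diff <- tapply(data$difficulty, data$pair_id, mean)
  d <- as.numeric(mean_diff[as.character(data$pair_id)])
  data$mean_difficulty <- (d - mean(mean_diff)) / stats::sd(mean_diff)
  aug <- fit_glmm(data, fit$response, c(fit$fixed, "mean_difficulty"),
                  fit$random, fit$family, fit$nAGQ)
  list(fit = aug, base = fit, lrt = lrt(aug, fit),
       note = paste("mean_difficulty is a subjective rating-based",
                    "predictor; interpret alongside, not instead of,",
                    "image-based predictors"))
}
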