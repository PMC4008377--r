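#!/usr/bin/env Rscript

# Stage 3: mixed-model analysis of per-trial correctness and ratings.
#
# Fits the crossed random-intercepts logistic model of correctness, compares
# random structures (the expertID term is dropped when every expert offset
# sits within two SE of zero), reduces the fixed effects by backward AIC
# elimination, tests the reduced model against the intercept-only null, and
# fits the linear mixed models for normalized response time, difficulty and
# confidence. Writes coefficient tables under results/.

library(printdiff)

study <- "results/study"
features <- read.csv(file.path(study, "features.csv"))
trials <- suppressMessages(read_trials(file.path(study, "trials_clean.csv")))

mains <- setdiff(intersect(
  c(paste0(rep(printdiff:::print_metric_names, each = 2), c("_L", "_K")),
    printdiff:::pair_metric_names), names(features)), character(0))
inter <- grep("_LxK$", names(features), value = TRUE)
binary <- intersect(c("core_L", "delta_L", "core_K", "delta_K"),
                    names(features))
fixed <- c(mains, binary, inter)
data <- merge(trials, features, by = "pair_id")

message("random-structure comparison ...")
structures <- compare_random_structures(data, "correct", fixed, nAGQ = 0)
print(structures$ic)
message(sprintf("LRT for expertID: chi2(%d) = %.2f, p = %.3f",
                structures$lrt_expert$df, structures$lrt_expert$chi2,
                structures$lrt_expert$p))
random <- if (structures$drop_expert) "pair_id" else
  c("pair_id", "expert_id")
message("expert offsets all within 2 SE of zero: ", structures$drop_expert,
        " -> random terms: ", paste(random, collapse = ", "))

message("backward AIC elimination over ", length(fixed), " predictors ...")
sel <- aic_backward_select(data, "correct", fixed, random, nAGQ = 0)
print(sel$trace)
fit <- fit_glmm(data, "correct", sel$fixed, random)  # final Laplace fit
null_fit <- fit_glmm(data, "correct", character(0), random)
lr <- lrt(fit, null_fit)
message(sprintf("reduced model vs null: chi2(%d) = %.2f, p = %.2g",
                lr$df, lr$chi2, lr$p))
print(fit)

ratings <- data[!is.na(data$difficulty), ]
ratings$norm_rt <- normalize_rt(ratings)
lmm_fixed <- intersect(fixed, names(ratings))
lmms <- lapply(c(norm_rt = "norm_rt", difficulty = "difficulty",
                 confidence = "confidence"), function(resp) {
  fit_lmm(ratings, resp, lmm_fixed)
})

dir.create("results", showWarnings = FALSE)
write.csv(fit$beta, "results/accuracy_model.csv", row.names = FALSE)
write.csv(sel$trace, "results/aic_trace.csv", row.names = FALSE)
for (nm in names(lmms)) {
  write.csv(lmms[[nm]]$beta, sprintf("results/lmm_%s.csv", nm),
            row.names = FALSE)
  message(sprintf("%s model: var_print %.3f, var_expert %.3f", nm,
                  lmms[[nm]]$var_print, lmms[[nm]]$var_expert))
}
writeLines(jsonlite::toJSON(list(
  selected = fit$fixed, var_print = fit$var_print,
  var_expert = fit$var_expert, aic = fit$aic,
  lrt_vs_null = lr, drop_expert = structures$drop_expert),
  auto_unbox = TRUE, pretty = TRUE, digits = NA),
  "results/accuracy_model.json")
message("wrote results/accuracy_model.{csv,json}")
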