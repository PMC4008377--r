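#!/usr/bin/env Rscript

# Stage 2: trial preprocessing and feature assembly.
#
# Reads the raw metric and trial tables written by 01_simulate_study.R,
# applies the decision-based trial exclusion rule, standardizes the
# continuous metrics, forms latent-x-known interactions, and runs the
# collinearity screen (|r| > 0.5 pairwise removal, then VIF < 5).

library(printdiff)

study <- "results/study"
raw <- read.csv(file.path(study, "raw_metrics.csv"))
trials <- read_trials(file.path(study, "trials.csv"))

features <- assemble_features(raw)
screened <- collinearity_filter(features)

message("collinearity screen removed ", nrow(screened$report),
        " predictor(s):")
print(screened$report)

write.csv(screened$features, file.path(study, "features.csv"),
          row.names = FALSE)
write.csv(screened$report, file.path(study, "collinearity_report.csv"),
          row.names = FALSE)
write_trials(trials, file.path(study, "trials_clean.csv"))
message("features: ", nrow(screened$features), " pairs x ",
        ncol(screened$features), " columns")
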