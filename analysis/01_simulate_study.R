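#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study bundle.
#
# Renders 200 latent/known print pairs (four Level I pattern classes, half
# matches, half same-class close non-matches), degrades the latents with
# sampled crop/smudge/contrast/noise parameters to spread the feature space,
# simulates an examiner panel from the crossed logistic model, and writes
# images, masks, annotations and the raw trial table under results/study/.
#
# At 200 pairs this run takes a few minutes end to end; the package
# functions run unchanged at other study sizes.

library(printdiff)

seed <- 20260919
n_pairs <- 200
out <- "results/study"
dir.create(file.path(out, "images"), recursive = TRUE, showWarnings = FALSE)

panel <- panel_config(experts_per_batch = 10, batch_size = 20)
message("building ", n_pairs, "-pair study (seed ", seed, ") ...")
bundle <- build_study(n_pairs = n_pairs, panel = panel, with_images = TRUE,
                      seed = seed, keep_prints = TRUE)

for (i in seq_along(bundle$prints)) {
  pid <- bundle$raw_metrics$pair_id[i]
  pr <- bundle$prints[[i]]
  write_print(pr$latent$image, file.path(out, "images",
                                         paste0(pid, "_latent.png")))
  write_print(pr$latent$mask, file.path(out, "images",
                                        paste0(pid, "_latent_mask.png")))
  write_print(pr$known$image, file.path(out, "images",
                                        paste0(pid, "_known.png")))
  write_print(pr$known$mask, file.path(out, "images",
                                       paste0(pid, "_known_mask.png")))
}
write.csv(bundle$annotations, file.path(out, "annotations.csv"),
          row.names = FALSE)
write.csv(bundle$raw_metrics, file.path(out, "raw_metrics.csv"),
          row.names = FALSE)
write_trials(bundle$raw_trials, file.path(out, "trials.csv"))

message(sprintf(
  "wrote %d pairs, %d raw trials (%d without a decision) to %s",
  n_pairs, nrow(bundle$raw_trials),
  sum(is.na(bundle$raw_trials$judged_match)), out))
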