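# printdiff

Latent fingerprint comparisons are not uniformly hard: a clear, complete
latent against a clean tenprint is easy, a smudged partial against a close
non-match is not, and examiner error concentrates on the hard ones. A
single error rate for the discipline is therefore too coarse. `printdiff`
implements an image-based difficulty pipeline for forensic researchers:
quantitative quality/information metrics computed on each print and on the
latent-known pair, a crossed mixed-effects logistic model of per-trial
examiner correctness, AIC-based model reduction, and a predicted-accuracy
threshold classifier that flags pairs likely to produce at least one
examiner error. A synthetic generator of fingerprint pairs and simulated
examiner panels makes the whole analysis runnable and testable without
access to restricted casework databases.

## The model

For print pair *i* and examiner *j*,

    y_ij ~ Bernoulli( logit^-1( b0 + X_i b + printID_i + expertID_j ) )

where `X_i` holds standardized image features — total area, area ratio,
intensity mean/SD, block-intensity SD, deviation from expected average
intensity (DEAI, `-(|mean − 127.5|)`), Michelson contrast
(`(Imax−Imin)/(Imax+Imin)`), block contrast mean/SD, oriented-filter ridge
reliability, the Euclidean ridge sum `sqrt(rL² + rK²)`, core/delta
visibility flags, and latent×known interactions — and `printID_i`,
`expertID_j` are crossed normal random intercepts for residual pair
difficulty and examiner baseline. Features pass a collinearity screen
(pairwise |r| > 0.5 removal, then VIF < 5) before fitting; fixed effects
are reduced by backward AIC elimination with interactions leaving before
their mains. Fitting uses the Laplace approximation (`lme4`); linear mixed
models of normalized response time and difficulty/confidence ratings use
the same machinery with a Gaussian response.

## Worked example

```r
library(printdiff)

# a clean known print and a degraded latent from the same source
known  <- generate_known(gen_config(pattern = "whorl", seed = 3))
latent <- degrade_to_latent(known, degrade_config(crop_fraction = 0.6,
                                                  n_smudges = 3, seed = 5))
ridge_reliability(known$image, known$mask)   # 0.9733333
ridge_reliability(latent$image, latent$mask) # 0.9111111
area_ratio(latent$mask, known$mask)          # 0.600021

# a 200-pair study with a simulated panel of 56 examiners, end to end
res <- run_study(n_pairs = 200, seed = 7, nAGQ = 0)
res$fit$var_print            # 2.04  (printID variance)
res$quality$r2_adj           # 0.92  in-sample predicted vs observed accuracy
res$quality$rmse             # 0.040 (intercept-only null: 0.154)
res$classifier$threshold     # 0.929 trained accuracy threshold
res$test_result$accuracy     # 0.90  held-out classification accuracy
```

The numbers shown are what those calls print under the given seeds. The
first block says the clean whorl has almost fully reliable ridge flow,
while cropping and smudging removed 40% of its area and part of its
reliable regions. In the study, per-pair observed accuracy is tracked
closely in sample (adjusted R² 0.92, RMSE 0.040 against 0.154 for the
intercept-only null) because seen pairs get their fitted printID
intercepts; the threshold classifier, trained only on the 180 training
pairs, labels 90% of the 20 held-out pairs correctly as perfect (no
examiner erred) vs non-perfect.

## Analysis workflow

The numbered drivers under `analysis/` run the study as a narrative
pipeline, writing tables and figures under `results/`:

1. `01_simulate_study.R` — render a 200-pair image-backed study (prints,
   masks, annotations, raw examiner trials);
2. `02_features.R` — trial exclusion rule, standardization, interactions,
   collinearity screen;
3. `03_fit_models.R` — random-structure comparison, backward AIC
   elimination, final crossed logistic fit, rating/RT linear mixed models;
4. `04_evaluate.R` — R²/RMSE, stratified 90/10 validation, threshold
   classifier, difficulty-augmented model, predicted-vs-observed scatter.

Each stage reads only the previous stage's files, so stages can be rerun
independently. `vignettes/predicting-comparison-difficulty.Rmd` documents
the metrics, the model, the generator and every numerical choice.

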