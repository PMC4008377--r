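---
title: "Predicting the difficulty of latent fingerprint comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the difficulty of latent fingerprint comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printdiff)
```

## The problem

Latent prints recovered from surfaces are partial, smudged and noisy;
known prints (tenprints) are collected under controlled conditions and are
usually clear. Trained examiners compare a latent against a candidate known
print and declare a match or a non-match. Their error rates are low but not
zero, and a single overall error rate is too coarse: some comparisons are
far harder than others. `printdiff` implements a pipeline that quantifies
comparison difficulty from the images alone: bespoke image metrics on each
print and on the pair, a crossed mixed-effects logistic model of per-trial
examiner correctness, AIC-based model reduction, and a predicted-accuracy
threshold classifier that flags pairs on which at least one examiner is
likely to err. Because the fingerprint databases and examiner panels such
studies use are not publicly deposited, the package ships a synthetic
generator of fingerprint pairs and simulated panels, so the whole analysis
runs end to end and every stage is testable.

## Image metrics

All metrics are computed on 8-bit grayscale rasters (0 = ridge ink,
255 = bright background; polarity is documented, never auto-inverted) over
a binary segmentation mask. Block statistics use 50 x 50 pixel tiles.

* **Total area** — in-mask pixel count; more friction-ridge area means more
  information. **Area ratio** divides latent area by known area; it can
  exceed 1 (different finger on a non-match, or smearing), so it is not a
  true proportion.
* **Image intensity** — in-mask mean and population SD. Dark means flag
  smudges; low SD flags washed-out ridge/valley transitions.
* **Block intensity SD** — SD across per-tile mean intensities; high when
  some regions are darker than others (local smudging, uneven contact).
* **DEAI** (deviation from expected average intensity) — an ideal print is
  about half ink and half valley, so the expected mean is 127.5; DEAI is
  `-(|mean - 127.5|)`, maximal (0) at the midpoint and equally penalizing
  deviations in either direction.
* **Michelson contrast** — `(Imax - Imin)/(Imax + Imin)` in [0, 1],
  computed on pixel intensity because display gamma is unknown. **Block
  contrast** is the same measure per tile, summarized by its mean and SD: a
  gray image with one white and one black pixel has global contrast 1 but
  near-zero mean block contrast, which is exactly the information the
  block version adds.
* **Ridge reliability** — the proportion of analysis windows whose dominant
  ridge orientation is uniquely specified (next section). The pair-level
  **ridge sum** is `sqrt(rL^2 + rK^2)`.
* **Cores and deltas** — binary Level I landmark visibility flags, taken
  from annotations.

### Block grid conventions

The tile grid is anchored at the top-left of the mask's bounding box, which
makes every block statistic exactly invariant to translating the print
within its canvas. A tile is retained iff at least 50% of its nominal
`50^2` pixels are in-mask, so boundary slivers cannot dominate the
across-block SDs. All statistics are computed over in-mask pixels only:
background is not fingerprint signal (a `--whole-canvas` fidelity variant
would change only `in_mask_pixels()` and was deliberately not exposed —
masks here are raster images, and an all-true mask reproduces it).

### The ridge-reliability operator

The operator is a structure-tensor-flavoured filter-bank design, fully
parameterized for sensitivity analysis: 16 x 16 analysis windows; 8
even-symmetric, zero-mean Gabor kernels spanning [0, pi) with carrier
wavelength 9 px (a typical ridge period at the working resolution) and
envelope SD 4 px; responses computed by FFT convolution after centering the
image. A window is "high reliability" when

1. its top orientation energy is at least `tau = 1.5` times the best
   **non-adjacent** orientation's energy, and
2. the top energy is at least `epsilon = 1%` of the **maximum possible**
   window energy, `n_window * (127.5 * sum(|g|))^2`.

Two numerical choices deserve explanation. The runner-up in the dominance
ratio excludes the two bins adjacent to the peak because a true orientation
midway between two bin centers necessarily splits its energy between them;
with the literal runner-up, a geometrically perfect whorl scores about
0.47 instead of ~0.97, purely as a binning artifact. And the energy floor
is expressed against the absolute response bound rather than the energy of
a matched full-contrast grating (which reaches only ~30% of that bound):
on this scale real ridge structure sits at 10-40% of the bound while
i.i.d. noise stays below 1%, so the 1% floor cleanly rejects unoriented
texture. With these defaults, clean synthetic prints score 0.95+, heavily
smudged latents drop monotonically with smudge coverage, and uniform noise
scores essentially 0.

## Feature assembly and collinearity screening

Continuous metrics are z-scored across the analysis cohort; for every
metric defined on both prints a latent-x-known interaction is formed as the
product of the standardized mains and then itself z-scored. The per-column
training means and SDs are persisted so held-out pairs are transformed with
training statistics. Binary core/delta flags stay 0/1.

The collinearity screen mirrors standard regression practice: while any
pair of continuous mains has |Pearson r| > 0.5, the member with the larger
mean absolute correlation to all other mains is removed (ties broken by
canonical column order — a deterministic rule, since the choice is
otherwise arbitrary); survivors must then show variance inflation factors
below 5. Interactions lose both parents or stay.

## The accuracy model

For pair *i* and examiner *j*, correctness is modeled as

$$y_{ij} \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}
  (\beta_0 + X_i\beta + \mathrm{printID}_i + \mathrm{expertID}_j)\right),$$

with crossed normal random intercepts for print pair and examiner.
Estimation is maximum likelihood with the Laplace approximation
(`lme4::glmer`); `nAGQ = 0` is available for large model scans and the
backward-elimination loop, with the final model always refitted at
`nAGQ = 1`. Wald statistics are reported but — following the usual caveat
about their degrees of freedom in unbalanced mixed designs — model
decisions rest on AIC and likelihood-ratio tests only.

The random-structure comparison fits crossed, print-only and expert-only
models, reports AIC/BIC and the 1-df likelihood-ratio test for the
examiner component, and recommends dropping `expertID` when every
examiner's predicted offset lies within two standard errors of zero.
Backward elimination greedily removes the fixed effect whose removal most
lowers AIC and stops when none does; by default an interaction must leave
the model before either of its mains can (the hierarchy keeps reduced
models interpretable; passing `hierarchy = list()` removes the
constraint). Ratings and response time get Gaussian analogues fitted by
REML, with response time z-scored per examiner first (examiners differ
greatly in pace; a global z-score is available).

A deliberate modeling point: predicted accuracy for a pair seen in fitting
includes its printID intercept (the model's estimate of that pair's
residual difficulty), while an unseen pair can only receive the
population-level inverse-logit of the fixed effects. In-sample fit quality
(adjusted R², RMSE) therefore looks much stronger than held-out quality
whenever the printID variance is large — which is exactly what the
validation split is for.

## Evaluation protocol

Observed accuracy per pair is the fraction of correct judgments across the
examiners who saw it; a **perfect pair** is one with observed accuracy
exactly 1. Fit quality uses `R^2 = 1 - SSE/SST` against observed per-pair
accuracy, adjusted as `1 - (1 - R^2)(n - 1)/(n - k - 1)` (`k` =
fixed-effect predictors; the adjustment formula is the standard one, chosen
here since nothing else is specified by convention), and RMSE. Validation
holds out 10% of pairs, stratified on perfect/non-perfect so the held-out
mix matches the population. The classifier sweeps every observed predicted
value (plus 0 and 1) as a threshold — no fixed grid, so a reported optimal
threshold is data- not grid-determined — and maximizes training
classification accuracy, breaking ties toward the higher threshold, the
conservative direction that flags more pairs as error-prone. Difficulty
ratings can be added as a per-pair mean predictor; the report flags them as
subjective, to be read alongside the image-based model rather than inside
it.

## The synthetic generator

`generate_known()` renders near-binary dark-ridge images from a smooth
phase field per Level I class: concentric circles for whorls (core at
center), confocal parabolas for loops (core at the focus, left/right by
mirroring), and bowed horizontal ridges for arches (no core, no delta).
Ridge period defaults to 9 px on a 192 px canvas with an elliptical print
boundary; centers, period and orientation jitter with the seed. Known
prints receive mild "inking" variation (contrast attenuation up to 30%,
intensity bias within ±12, grain noise), so known-side metrics vary across
prints as real inked tenprints do.

`degrade_to_latent()` applies, in order: a crop that keeps the requested
fraction of in-mask pixels nearest a random interior point; super-Gaussian
(plateau-profile) smudge blobs that multiply intensity toward ink — the
plateau matters, because a plain Gaussian blob nulls ridge contrast only
at its very center and barely moves the reliability score; a smooth random
contrast-attenuation field; a global intensity bias; additive Gaussian
noise; and a clip back to [0, 255].

`simulate_panel()` draws examiner responses from the accuracy model itself
in its generative direction. Defaults are the study conditions the
analysis assumes: a pool of 56 examiners, batches of 20 pairs (ten match,
ten same-class close non-match) each completed by ~10 examiners (~2,000 to
2,400 trials at 200 pairs), intercept 3.385, slopes of Table-2 scale on
six features, printID variance 2.154, and a small expertID variance of 0.2
(examiner offsets within two SE of zero — present, but small enough that
the random-structure comparison usually recommends dropping the term, as
intended). About 1% of trials time out with no decision and 0.5% lose
their ratings after a decision, exercising the exclusion rule. Ratings use
a simple monotone link — difficulty `round(4.6 - 0.75*eta_pair + noise)`
clipped to 1-6, confidence `7 - difficulty` plus noise, log-normal
response time increasing in difficulty — documented, not claimed
realistic; they produce the strong difficulty-confidence anticorrelation
the analysis expects. Ground-truth difficulty is injected through the
features themselves (degradation -> metrics -> X*beta), not through a
hidden difficulty variable, so refitting the model on generated data tests
the entire measurement chain; the printID variance captures residual pair
difficulty beyond the features, exactly the term's role in the model.

`simulate_raw_metrics()` is a feature-level shortcut for model-scale
experiments: each metric responds to a 50/50 blend of a shared pair
severity and an independent component (emulating stimuli selected to
spread every feature axis), with known-side metrics varying narrowly. All
metric range invariants hold on its output, and the induced correlation
structure triggers the collinearity screen only on the structurally
redundant columns (total area vs area ratio, reliability vs ridge sum).

## What the synthetic data do and do not show

Passing tests on synthetic studies demonstrate that the pipeline measures
what it claims on images with known ground truth, that the crossed model
recovers its generating parameters at study scale (200 pairs, ~11
examiners per pair, printID variance ~2), that backward elimination
retains truly informative predictors, and that the threshold classifier
transfers above the naive baseline. They do not show that these particular
metrics predict human examiner performance on real casework: synthetic
ridges lack minutiae-level structure, elastic skin distortion, background
clutter and the examiner's perceptual strategies. The package is the
instrument; conclusions about real examiners require real data.

## Numerical choices and problem sizes

Degenerate inputs are defined, not crashed on: an all-zero image has
Michelson contrast 0 (with a warning); fewer than two retained blocks give
a missing across-block SD; a constant response raises a separation error;
coefficients diverging past |beta| = 15 are reported as separation naming
the column. Convergence issues in `glmer` are flagged on the returned
object, never silent; variance estimates on the zero boundary are
legitimate fits and are not flagged. The test suite runs its simulation
checks at 200 pairs x 11 examiners (parameter recovery, 50 replicates),
80 pairs x 8 examiners (selection, 50 replicates) and 25 simulated studies
for the classifier protocol; the analysis scripts under `analysis/` render
a 200-pair image-backed study as a demonstration, and all functions run
unchanged at larger sizes.
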