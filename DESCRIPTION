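Package: printdiff
Title: Predicting the Difficulty of Latent Fingerprint Comparisons from
    Image Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative image metrics for latent and known fingerprint
    images (area, intensity and block-intensity statistics, deviation from
    expected average intensity, Michelson and block-wise contrast, ridge
    orientation reliability from an oriented filter bank), feature assembly
    with standardization, two-way latent-by-known interactions and a
    collinearity screen, crossed random-intercepts logistic regression of
    per-trial examiner correctness with likelihood-ratio tests and AIC
    backward elimination, linear mixed models for response time and
    difficulty/confidence ratings, per-pair accuracy evaluation with a
    stratified train/test split and a predicted-accuracy threshold
    classifier, and a synthetic generator of fingerprint pairs and simulated
    examiner panels so the whole analysis runs without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    png,
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ggplot2
Config/testthat/edition: 3
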