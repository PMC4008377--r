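# Synthetic fingerprint pairs and simulated examiner panels.
#
# Known prints are rendered as near-binary dark-ridge images from a smooth
# phase field whose level sets follow the Level I pattern class: concentric
# circles for whorls (core at center), confocal parabolas for loops (core at
# the focus), and bowed horizontal ridges for arches (no core). Latents are
# degraded copies: cropped, smudged, contrast-attenuated, biased and noisy.
# Examiner panels are drawn from the crossed logistic model itself, so
# refitting the model on a generated study is a parameter-recovery test of
# the entire measurement chain.

#' Configuration for a synthetic known print
#'
#' @param size Canvas side in pixels.
#' @param wavelength Ridge period in pixels at the reference radius.
#' @param pattern One of `"arch"`, `"left-loop"`, `"right-loop"`, `"whorl"`.
#' @param delta_present Is a delta visible? Forced `FALSE` for arches.
#' @param seed Integer seed; the same seed gives byte-identical images.
#' @param id Print identifier.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(size = 192, wavelength = 9,
                       pattern = c("whorl", "left-loop", "right-loop",
                                   "arch"),
                       delta_present = NULL, seed = 1, id = NULL) {
  pattern <- match.arg(pattern)
  if (is.null(delta_present)) delta_present <- pattern != "arch"
  if (pattern == "arch") delta_present <- FALSE
  if (is.null(id)) id <- sprintf("%s_%d", pattern, seed)
  structure(list(size = size, wavelength = wavelength, pattern = pattern,
                 delta_present = delta_present, seed = seed, id = id),
            class = "gen_config")
}

#' Generate a clean synthetic known print
#'
#' @param config A [gen_config].
#' @return List with `image` (a [print_image], role `"known"`), `mask`
#'   (elliptical print boundary) and `annotation` (`core_present`,
#'   `delta_present`, `core_type`).
#' @export
generate_known <- function(config) {
  if (!inherits(config, "gen_config")) stop("config must be a gen_config")
  n <- config$size
  with_seed(config$seed, {
    cx <- n / 2 + stats::runif(1, -n / 16, n / 16)
    cy <- n / 2 + stats::runif(1, -n / 16, n / 16)
    lambda <- config$wavelength * stats::runif(1, 0.9, 1.1)
    rot <- stats::runif(1, -pi / 12, pi / 12)
    x <- matrix(rep(seq_len(n), each = n), n) - cx   # column coordinate
    y <- matrix(rep(seq_len(n), n), n) - cy          # row coordinate
    xr <- cos(rot) * x + sin(rot) * y
    yr <- -sin(rot) * x + cos(rot) * y
    psi <- switch(config$pattern,
      whorl = 2 * pi * sqrt(xr^2 + yr^2) / lambda,
      "right-loop" = {
        z <- complex(real = yr, imaginary = xr)      # parabolas open down
        r0 <- n / 4
        2 * pi / lambda * 2 * sqrt(r0) * Im(sqrt(z))
      },
      "left-loop" = {
        z <- complex(real = yr, imaginary = -xr)
        r0 <- n / 4
        2 * pi / lambda * 2 * sqrt(r0) * Im(sqrt(z))
      },
      arch = 2 * pi / lambda *
        (yr - (n / 6) * exp(-xr^2 / (2 * (n / 5)^2)))
    )
    psi <- matrix(psi, n, n)   # complex() drops dims for the loop classes
    # near-binary ridges: dark (low intensity) where cos(psi) > 0
    img <- round(127.5 - 127.5 * tanh(3 * cos(psi)))
    a <- 0.44 * n * stats::runif(1, 0.92, 1)
    b <- 0.40 * n * stats::runif(1, 0.92, 1)
    mask <- (x / a)^2 + (y / b)^2 <= 1
    img[!mask] <- 255
    list(image = print_image(pmin(pmax(img, 0), 255), role = "known",
                             id = config$id),
         mask = mask,
         annotation = list(core_present = config$pattern != "arch",
                           delta_present = config$delta_present,
                           core_type = if (config$pattern != "arch")
                             config$pattern else NA_character_))
  })
}

#' Degradation parameters for turning a known print into a latent
#'
#' Defaults are a moderate degradation; `degrade_config(crop_fraction = 1,
#' n_smudges = 0, contrast_attenuation = 0, intensity_bias = 0,
#' noise_sd = 0)` is the identity.
#'
#' @param crop_fraction Target fraction of the print area retained (0, 1\].
#' @param n_smudges Number of Gaussian smudge blobs.
#' @param smudge_radius Smudge SD in pixels.
#' @param smudge_strength Peak darkening fraction of each smudge (0-1).
#' @param contrast_attenuation Peak multiplicative contrast loss (0-1),
#'   applied through a smooth random field.
#' @param intensity_bias Additive global intensity shift.
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param seed Integer seed.
#' @return A list of class `degrade_config`.
#' @export
degrade_config <- function(crop_fraction = 0.6, n_smudges = 3,
                           smudge_radius = 16, smudge_strength = 0.95,
                           contrast_attenuation = 0.3, intensity_bias = 0,
                           noise_sd = 5, seed = 1) {
  stopifnot(crop_fraction > 0, crop_fraction <= 1, n_smudges >= 0,
            smudge_radius > 0, smudge_strength >= 0, smudge_strength <= 1,
            contrast_attenuation >= 0, contrast_attenuation <= 1,
            noise_sd >= 0)
  structure(as.list(environment()), class = "degrade_config")
}

# smooth random field in [0,1]: bilinear upsampling of a coarse uniform grid
smooth_field <- function(n, cells = 6) {
  g <- matrix(stats::runif((cells + 1)^2), cells + 1)
  idx <- seq(0, cells, length.out = n)
  i0 <- pmin(floor(idx) + 1L, cells)
  fr <- idx - (i0 - 1L)
  row_interp <- g[i0, , drop = FALSE] * (1 - fr) +
    g[i0 + 1L, , drop = FALSE] * fr
  out <- row_interp[, i0, drop = FALSE] * rep(1 - fr, each = n) +
    row_interp[, i0 + 1L, drop = FALSE] * rep(fr, each = n)
  out
}

#' Degrade a known print into a latent
#'
#' Applies, in order: a sub-region crop (reducing total area to roughly
#' `crop_fraction` of the original), Gaussian smudge blobs that push local
#' intensity toward dark ink and destroy ridge orientation, a smooth
#' multiplicative contrast-attenuation field, a global intensity bias, and
#' additive Gaussian noise; intensities are clipped back to \[0, 255\].
#'
#' @param known List with `image` and `mask` from [generate_known].
#' @param config A [degrade_config].
#' @return List with `image` (role `"latent"`) and `mask` (cropped).
#' @export
degrade_to_latent <- function(known, config) {
  if (!inherits(config, "degrade_config")) {
    stop("config must be a degrade_config")
  }
  px <- known$image$pixels + 0
  mask <- known$mask
  n <- nrow(px)
  with_seed(config$seed, {
    if (config$crop_fraction < 1) {
      area <- sum(mask)
      inside <- which(mask, arr.ind = TRUE)
      # center the crop on a point in the middle of the print, then keep
      # the crop_fraction of in-mask pixels nearest to it, so the retained
      # area hits the target even when the crop disc leaves the print
      ctr <- colMeans(inside)
      cand <- inside[
        (inside[, 1] - ctr[1])^2 + (inside[, 2] - ctr[2])^2 <
          area / pi, , drop = FALSE]
      if (nrow(cand) == 0L) cand <- inside
      pick <- cand[sample.int(nrow(cand), 1), ]
      d2 <- (inside[, 1] - pick[1])^2 + (inside[, 2] - pick[2])^2
      r2 <- stats::quantile(d2, config$crop_fraction, type = 1)
      rr <- matrix(rep(seq_len(n), ncol(px)), n) - pick[1]
      cc <- matrix(rep(seq_len(ncol(px)), each = n), n) - pick[2]
      mask <- mask & (rr^2 + cc^2 <= r2)
      if (!any(mask)) stop("crop produced an empty mask")
      px[!mask] <- 255
    }
    if (config$n_smudges > 0) {
      inside <- which(mask, arr.ind = TRUE)
      for (s in seq_len(config$n_smudges)) {
        pick <- inside[sample.int(nrow(inside), 1), ]
        rr <- matrix(rep(seq_len(n), ncol(px)), n) - pick[1]
        cc <- matrix(rep(seq_len(ncol(px)), each = n), n) - pick[2]
        # plateau profile: near-full strength across the blob radius, so a
        # smudge flattens ridge contrast over its whole footprint the way
        # an ink blot does, rather than only at its very center
        blob <- exp(-0.5 * ((rr^2 + cc^2) / config$smudge_radius^2)^3)
        px <- px * (1 - config$smudge_strength * blob)
      }
    }
    if (config$contrast_attenuation > 0) {
      field <- 1 - config$contrast_attenuation * smooth_field(n)[
        seq_len(nrow(px)), seq_len(ncol(px)), drop = FALSE]
      px <- 127.5 + field * (px - 127.5)
    }
    px <- px + config$intensity_bias
    if (config$noise_sd > 0) {
      px <- px + matrix(stats::rnorm(length(px), 0, config$noise_sd),
                        nrow(px))
    }
    px <- round(pmin(pmax(px, 0), 255))
    px[!mask] <- 255
    list(image = print_image(px, role = "latent",
                             id = paste0(known$image$id, "_latent")),
         mask = mask)
  })
}

#' Configuration for a simulated examiner panel
#'
#' Defaults follow the study design the analysis assumes: a pool of 56
#' examiners, batches of 20 pairs (ten match, ten non-match) each completed
#' by about ten examiners, a logistic intercept of 3.385 and printID
#' variance 2.154 (the scale of the fitted accuracy model), and a small
#' expertID variance of 0.2 reflecting examiner offsets that sit within two
#' standard errors of zero.
#'
#' @param beta0 Logistic intercept.
#' @param beta Named vector of fixed-effect slopes over feature columns.
#' @param var_print,var_expert Random-intercept variances.
#' @param n_experts Size of the examiner pool.
#' @param experts_per_batch Examiners completing each batch.
#' @param batch_size Pairs per batch (half match / half non-match).
#' @param p_no_decision Probability a trial times out with no decision
#'   (such trials are excluded downstream).
#' @param p_missing_ratings Probability a decided trial times out before
#'   the ratings (retained with ratings absent).
#' @param seed Integer seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(beta0 = 3.385,
                         beta = c(delta_L = 0.798,
                                  mean_block_contrast_K = 0.534,
                                  area_ratio = -0.471,
                                  sd_block_contrast_LxK = -0.451,
                                  ridge_sum = 0.419,
                                  deai_LxK = 0.334),
                         var_print = 2.154, var_expert = 0.2,
                         n_experts = 56, experts_per_batch = 10,
                         batch_size = 20, p_no_decision = 0.01,
                         p_missing_ratings = 0.005, seed = 1) {
  stopifnot(var_print >= 0, var_expert >= 0, experts_per_batch >= 1,
            n_experts >= experts_per_batch, batch_size >= 1)
  structure(as.list(environment()), class = "panel_config")
}

#' Simulate an examiner panel over a set of feature rows
#'
#' Draws printID and expertID intercept offsets, then per trial a correct /
#' incorrect judgment from the crossed logistic model. Difficulty ratings
#' decrease in the pair's linear predictor (discretized to 1-6), confidence
#' is 7 minus difficulty plus independent noise (clipped to 1-6), and
#' response time is log-normal and increasing in difficulty. Pairs are
#' grouped into batches of `batch_size` balanced on match status; each batch
#' is completed by `experts_per_batch` examiners drawn from the pool.
#'
#' @param features Standardized feature table (from [assemble_features])
#'   with `pair_id`, `is_match` and every column named in `config$beta`.
#' @param config A [panel_config].
#' @return A raw trial data.frame (one row per pair x examiner) in the
#'   layout [read_trials] expects; pass through [clean_trials] to apply the
#'   exclusion rule.
#' @export
simulate_panel <- function(features, config = panel_config()) {
  if (!inherits(config, "panel_config")) stop("config must be a panel_config")
  miss <- setdiff(names(config$beta), names(features))
  if (length(miss)) {
    stop("features lack column(s): ", paste(miss, collapse = ", "))
  }
  for (nm in names(config$beta)) {
    v <- features[[nm]]
    if (length(unique(v)) > 2L &&
        (abs(mean(v)) > 1 || stats::sd(v) > 3)) {
      stop("feature column '", nm, "' does not look standardized")
    }
  }
  n_pairs <- nrow(features)
  is_match <- if ("is_match" %in% names(features)) features$is_match else
    rep(TRUE, n_pairs)
  with_seed(config$seed, {
    xb <- rep(config$beta0, n_pairs)
    for (nm in names(config$beta)) {
      xb <- xb + config$beta[[nm]] * features[[nm]]
    }
    u <- stats::rnorm(n_pairs, 0, sqrt(config$var_print))
    v <- stats::rnorm(config$n_experts, 0, sqrt(config$var_expert))

    # batches balanced on match status
    ord <- c(rbind(sample(which(is_match)),
                   sample(which(!is_match))))[seq_len(n_pairs)]
    n_batches <- ceiling(n_pairs / config$batch_size)
    rows <- vector("list", n_batches)
    for (b in seq_len(n_batches)) {
      idx <- ord[((b - 1) * config$batch_size + 1):
                   min(b * config$batch_size, n_pairs)]
      experts <- sample.int(config$n_experts, config$experts_per_batch)
      rows[[b]] <- expand.grid(pair = idx, expert = experts)
    }
    grid <- do.call(rbind, rows)
    eta <- xb[grid$pair] + u[grid$pair] + v[grid$expert]
    correct <- stats::rbinom(nrow(grid), 1, stats::plogis(eta))
    eta_pair <- xb[grid$pair] + u[grid$pair]
    difficulty <- pmin(pmax(round(4.6 - 0.75 * eta_pair +
                                    stats::rnorm(nrow(grid), 0, 0.9)),
                            1), 6)
    confidence <- pmin(pmax(round(7 - difficulty +
                                    stats::rnorm(nrow(grid), 0, 0.7)),
                            1), 6)
    response_time <- pmin(exp(log(25) + 0.25 * (difficulty - 3) +
                                stats::rnorm(nrow(grid), 0, 0.35)), 180)
    pm <- is_match[grid$pair]
    judged <- ifelse(correct == 1, pm, !pm)
    no_decision <- stats::runif(nrow(grid)) < config$p_no_decision
    no_ratings <- !no_decision &
      stats::runif(nrow(grid)) < config$p_missing_ratings
    trials <- data.frame(
      pair_id = as.character(features$pair_id[grid$pair]),
      expert_id = sprintf("E%02d", grid$expert),
      is_match = pm,
      judged_match = ifelse(no_decision, NA, judged),
      difficulty = ifelse(no_ratings, NA, difficulty),
      confidence = ifelse(no_ratings, NA, confidence),
      response_time = ifelse(no_decision, 180, response_time),
      timed_out = no_decision | no_ratings,
      stringsAsFactors = FALSE
    )
    trials$correct <- as.integer(trials$judged_match == trials$is_match)
    rownames(trials) <- NULL
    trials
  })
}

#' Feature-level study generator (no images)
#'
#' Draws a plausible raw metric table directly: each pair gets a latent
#' degradation severity spread uniformly over its range, which drives the
#' latent-side metrics; known-side metrics vary narrowly as known prints do.
#' Used for model-level experiments where rendering images would add cost
#' but no information. All metric range invariants hold on the output.
#'
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#' @return Raw metric data.frame in the layout of [pair_metrics] rows.
#' @export
simulate_raw_metrics <- function(n_pairs = 200, seed = 1) {
  with_seed(seed, {
    s <- stats::runif(n_pairs)    # shared latent degradation severity
    # each metric responds to its own blend of the shared severity and an
    # independent component, emulating stimuli chosen to spread every
    # feature axis rather than lie on one quality gradient
    sev <- function() pmin(pmax(0.5 * s + 0.5 * stats::runif(n_pairs),
                                0), 1)
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    ta_K <- round(stats::runif(n_pairs, 26000, 34000))
    ta_L <- pmax(round(ta_K * (1.05 - 0.75 * sev()) *
                         stats::runif(n_pairs, 0.85, 1.2)), 500)
    mi_L <- 127.5 + 70 * (sev() - 0.5) + stats::rnorm(n_pairs, 0, 12)
    mi_K <- 127.5 + stats::rnorm(n_pairs, 3, 8)
    raw <- data.frame(
      pair_id = sprintf("P%03d", seq_len(n_pairs)),
      is_match = rep(c(TRUE, FALSE), length.out = n_pairs),
      total_area_L = ta_L, total_area_K = ta_K,
      mean_intensity_L = mi_L, mean_intensity_K = mi_K,
      sd_intensity_L = pmax(110 * (1 - 0.6 * sev()) +
                              stats::rnorm(n_pairs, 0, 8), 5),
      sd_intensity_K = 115 + stats::rnorm(n_pairs, 0, 6),
      sd_block_intensity_L = pmax(12 + 35 * sev() +
                                    stats::rnorm(n_pairs, 0, 5), 0),
      sd_block_intensity_K = pmax(10 + stats::rnorm(n_pairs, 0, 3), 0),
      deai_L = -abs(mi_L - 127.5), deai_K = -abs(mi_K - 127.5),
      michelson_L = clamp01(1 - 0.25 * sev() * stats::runif(n_pairs)),
      michelson_K = clamp01(stats::runif(n_pairs, 0.97, 1)),
      mean_block_contrast_L = clamp01(0.9 - 0.55 * sev() +
                                        stats::rnorm(n_pairs, 0, 0.06)),
      mean_block_contrast_K = clamp01(0.88 + stats::rnorm(n_pairs, 0, 0.05)),
      sd_block_contrast_L = clamp01(0.08 + 0.2 * sev() +
                                      stats::rnorm(n_pairs, 0, 0.04)),
      sd_block_contrast_K = clamp01(0.06 + stats::rnorm(n_pairs, 0, 0.02)),
      ridge_reliability_L = clamp01(0.92 - 0.75 * sev() +
                                      stats::rnorm(n_pairs, 0, 0.07)),
      ridge_reliability_K = clamp01(stats::runif(n_pairs, 0.8, 0.98)),
      core_L = stats::rbinom(n_pairs, 1, clamp01(0.85 - 0.5 * s)),
      delta_L = stats::rbinom(n_pairs, 1, clamp01(0.6 - 0.4 * s)),
      core_K = stats::rbinom(n_pairs, 1, 0.95),
      delta_K = stats::rbinom(n_pairs, 1, 0.8)
    )
    raw$area_ratio <- raw$total_area_L / raw$total_area_K
    raw$ridge_sum <- sqrt(raw$ridge_reliability_L^2 +
                            raw$ridge_reliability_K^2)
    raw
  })
}

#' Generate a complete synthetic study bundle
#'
#' Known prints, degraded latents (degradation parameters sampled to spread
#' the feature space), per-pair metrics, standardized features and a
#' simulated examiner panel. Non-match pairs use a same-class print from a
#' different seed, emulating close non-matches. With `with_images = FALSE`
#' the raw metrics come from [simulate_raw_metrics] instead of rendered
#' images.
#'
#' @param n_pairs Number of latent/known pairs (default 200).
#' @param panel A [panel_config] (its seed is overridden from `seed`).
#' @param with_images Render and measure actual images? Default TRUE.
#' @param image_size Canvas side for rendered prints.
#' @param seed Master seed; per-stage seeds are derived via [stage_seed].
#' @param keep_prints Keep the image arrays in the bundle (memory-heavy).
#' @return List: `raw_metrics`, `features`, `trials` (cleaned),
#'   `raw_trials`, `annotations`, `truth` (generating parameters), and
#'   `prints` when kept.
#' @export
build_study <- function(n_pairs = 200, panel = panel_config(),
                        with_images = TRUE, image_size = 192, seed = 1,
                        keep_prints = FALSE) {
  classes <- c("whorl", "left-loop", "right-loop", "arch")
  if (with_images) {
    raw <- NULL
    prints <- if (keep_prints) vector("list", n_pairs) else NULL
    ann <- NULL
    rows <- vector("list", n_pairs)
    par_seed <- stage_seed(seed, "degradation")
    pars <- with_seed(par_seed, data.frame(
      crop_fraction = stats::runif(n_pairs, 0.35, 1),
      n_smudges = sample(0:8, n_pairs, replace = TRUE),
      smudge_radius = stats::runif(n_pairs, 8, 22),
      contrast_attenuation = stats::runif(n_pairs, 0, 0.6),
      intensity_bias = stats::runif(n_pairs, -30, 30),
      noise_sd = stats::runif(n_pairs, 2, 12)
    ))
    is_match <- rep(c(TRUE, FALSE), length.out = n_pairs)
    # known prints carry mild inking variation (contrast, bias, grain), so
    # known-side metrics vary across prints as real inked tenprints do
    ink_known <- function(print, iseed) {
      cfg <- with_seed(iseed, degrade_config(
        crop_fraction = 1, n_smudges = 0,
        contrast_attenuation = stats::runif(1, 0.05, 0.3),
        intensity_bias = stats::runif(1, -12, 12),
        noise_sd = stats::runif(1, 1, 5),
        seed = stage_seed(iseed, "ink")))
      out <- degrade_to_latent(print, cfg)
      list(image = print_image(out$image$pixels, "known", print$image$id),
           mask = out$mask, annotation = print$annotation)
    }
    for (i in seq_len(n_pairs)) {
      cls <- classes[(i - 1) %% length(classes) + 1]
      src_seed <- stage_seed(seed, paste0("source", i))
      source_cfg <- gen_config(size = image_size, pattern = cls,
                               seed = src_seed,
                               id = sprintf("P%03d_src", i))
      source <- generate_known(source_cfg)
      latent <- degrade_to_latent(source, degrade_config(
        crop_fraction = pars$crop_fraction[i],
        n_smudges = pars$n_smudges[i],
        smudge_radius = pars$smudge_radius[i],
        smudge_strength = 0.95,
        contrast_attenuation = pars$contrast_attenuation[i],
        intensity_bias = pars$intensity_bias[i],
        noise_sd = pars$noise_sd[i],
        seed = stage_seed(seed, paste0("degrade", i))))
      known <- if (is_match[i]) source else
        generate_known(gen_config(size = image_size, pattern = cls,
                                  seed = stage_seed(seed,
                                                    paste0("nonmatch", i)),
                                  id = sprintf("P%03d_known", i)))
      known <- ink_known(known, stage_seed(seed, paste0("inkseed", i)))
      ann_latent <- source$annotation
      # heavy degradation can hide the latent's landmarks
      if (pars$crop_fraction[i] < 0.5) {
        ann_latent$core_present <- ann_latent$core_present &&
          pars$crop_fraction[i] > 0.4
        ann_latent$delta_present <- FALSE
      }
      rows[[i]] <- pair_metrics(latent, known, ann_latent,
                                known$annotation,
                                pair_id = sprintf("P%03d", i),
                                is_match = is_match[i])
      ann <- rbind(ann, data.frame(
        id = sprintf("P%03d", i), pattern = cls,
        core_L = ann_latent$core_present, delta_L = ann_latent$delta_present,
        core_K = known$annotation$core_present,
        delta_K = known$annotation$delta_present))
      if (keep_prints) prints[[i]] <- list(latent = latent, known = known)
    }
    raw <- do.call(rbind, rows)
  } else {
    prints <- NULL
    ann <- NULL
    raw <- simulate_raw_metrics(n_pairs, stage_seed(seed, "metrics"))
  }
  features <- assemble_features(raw)
  missing_beta <- setdiff(names(panel$beta), names(features))
  if (length(missing_beta)) {
    stop("panel model terms absent from the feature table (likely ",
         "zero-variance at this study size): ",
         paste(missing_beta, collapse = ", "))
  }
  panel$seed <- stage_seed(seed, "panel")
  raw_trials <- simulate_panel(features, panel)
  trials <- suppressMessages(clean_trials(raw_trials))
  out <- list(raw_metrics = raw, features = features, trials = trials,
              raw_trials = raw_trials, annotations = ann,
              truth = panel)
  if (keep_prints) out$prints <- prints
  out
}
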