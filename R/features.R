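# Feature assembly: per-print metrics -> per-pair predictor table with
# standardization, latent-x-known interactions and a collinearity screen.

print_metric_names <- c("total_area", "mean_intensity", "sd_intensity",
                        "sd_block_intensity", "deai", "michelson",
                        "mean_block_contrast", "sd_block_contrast",
                        "ridge_reliability")
pair_metric_names <- c("area_ratio", "ridge_sum")

#' Compute every single-print metric for one image
#'
#' @inheritParams intensity_stats
#' @param annotation Optional list/row with `core_present`, `delta_present`.
#' @param block_size Tile side for block statistics (default 50).
#' @param rr Named list of [ridge_reliability] parameters to override.
#' @return One-row data.frame with the single-print metric columns plus
#'   `core_present` and `delta_present`.
#' @export
single_print_metrics <- function(image, mask, annotation = NULL,
                                 block_size = 50, rr = list()) {
  it <- intensity_stats(image, mask)
  bc <- block_contrast(image, mask, block_size)
  rel <- do.call(ridge_reliability, c(list(image = image, mask = mask), rr))
  data.frame(
    total_area = total_area(mask),
    mean_intensity = unname(it["mean"]),
    sd_intensity = unname(it["sd"]),
    sd_block_intensity = block_intensity_sd(image, mask, block_size),
    deai = deai(image, mask),
    michelson = michelson(image, mask),
    mean_block_contrast = unname(bc["mean"]),
    sd_block_contrast = unname(bc["sd"]),
    ridge_reliability = rel,
    core_present = isTRUE(annotation$core_present),
    delta_present = isTRUE(annotation$delta_present)
  )
}

#' Raw (unstandardized) metric row for one latent/known pair
#'
#' Single-print metrics for both prints (suffixes `_L` and `_K`), the pair
#' metrics `area_ratio` and `ridge_sum`, and 0/1 core/delta flags.
#'
#' @param latent,known Lists with elements `image`, `mask` (as returned by
#'   [read_print] or [generate_known]).
#' @param ann_latent,ann_known Annotations with `core_present`,
#'   `delta_present`.
#' @param pair_id Pair identifier.
#' @param is_match Logical ground truth for the pair.
#' @param ... Passed to [single_print_metrics].
#' @return One-row data.frame.
#' @export
pair_metrics <- function(latent, known, ann_latent, ann_known,
                         pair_id, is_match, ...) {
  mL <- single_print_metrics(latent$image, latent$mask, ann_latent, ...)
  mK <- single_print_metrics(known$image, known$mask, ann_known, ...)
  row <- data.frame(pair_id = pair_id, is_match = is_match)
  for (nm in print_metric_names) {
    row[[paste0(nm, "_L")]] <- mL[[nm]]
    row[[paste0(nm, "_K")]] <- mK[[nm]]
  }
  row$area_ratio <- area_ratio(latent$mask, known$mask)
  row$ridge_sum <- ridge_sum(mL$ridge_reliability, mK$ridge_reliability)
  row$core_L <- as.integer(mL$core_present)
  row$delta_L <- as.integer(mL$delta_present)
  row$core_K <- as.integer(mK$core_present)
  row$delta_K <- as.integer(mK$delta_present)
  row
}

zscore <- function(x, center, scale) (x - center) / scale

#' Standardize a raw metric table and add latent-x-known interactions
#'
#' Continuous columns are z-scored across the pair set (zero-variance
#' columns are dropped with a warning). For every metric defined on both
#' prints, a `<metric>_LxK` interaction column is formed as the elementwise
#' product of the two standardized mains and then itself z-scored. Binary
#' core/delta flags are left 0/1. Rows with any missing metric are flagged
#' and excluded (reported via `message()`). The per-column training means
#' and SDs are stored in the `"standardization"` attribute so held-out
#' pairs can be transformed with training statistics (see
#' [apply_standardization]).
#'
#' @param raw Data.frame from [pair_metrics] rows (must include `pair_id`).
#' @param interactions Add latent-x-known interaction columns? Default TRUE.
#' @return Standardized feature data.frame with attributes
#'   `"standardization"`, `"continuous_mains"`, `"binary"`, `"excluded"`.
#' @export
assemble_features <- function(raw, interactions = TRUE) {
  binary <- intersect(c("core_L", "delta_L", "core_K", "delta_K"),
                      names(raw))
  mains <- intersect(c(paste0(rep(print_metric_names, each = 2),
                              c("_L", "_K")), pair_metric_names),
                     names(raw))
  metric_cols <- c(mains, binary)
  bad <- rowSums(is.na(raw[metric_cols])) > 0
  if (any(bad)) {
    message("excluding ", sum(bad), " pair(s) with missing metrics: ",
            paste(raw$pair_id[bad], collapse = ", "))
  }
  out <- raw[!bad, , drop = FALSE]
  if (nrow(out) < 2L) stop("need at least 2 complete pairs to standardize")

  center <- vapply(out[mains], mean, numeric(1))
  scale <- vapply(out[mains], stats::sd, numeric(1))
  degenerate <- scale < 1e-12
  if (any(degenerate)) {
    warning("dropping zero-variance column(s): ",
            paste(mains[degenerate], collapse = ", "))
    mains <- mains[!degenerate]
    center <- center[!degenerate]
    scale <- scale[!degenerate]
  }
  for (nm in mains) out[[nm]] <- zscore(out[[nm]], center[nm], scale[nm])

  inter_bases <- character(0)
  icenter <- numeric(0)
  iscale <- numeric(0)
  if (interactions) {
    for (base in print_metric_names) {
      cl <- paste0(base, "_L"); ck <- paste0(base, "_K")
      if (!(cl %in% mains) || !(ck %in% mains)) next
      prod_col <- out[[cl]] * out[[ck]]
      ic <- mean(prod_col); isd <- stats::sd(prod_col)
      if (isd < 1e-12) {
        warning("dropping zero-variance interaction: ", base, "_LxK")
        next
      }
      out[[paste0(base, "_LxK")]] <- zscore(prod_col, ic, isd)
      inter_bases <- c(inter_bases, base)
      icenter[paste0(base, "_LxK")] <- ic
      iscale[paste0(base, "_LxK")] <- isd
    }
  }
  rownames(out) <- NULL
  structure(out,
            standardization = list(center = center, scale = scale,
                                   interaction_bases = inter_bases,
                                   interaction_center = icenter,
                                   interaction_scale = iscale),
            continuous_mains = mains,
            binary = binary,
            excluded = raw$pair_id[bad])
}

#' Transform new raw metric rows with training standardization statistics
#'
#' @param raw New rows from [pair_metrics].
#' @param features A table produced by [assemble_features] (its
#'   `"standardization"` attribute supplies the training means/SDs).
#' @return Data.frame with the same feature columns as `features`.
#' @export
apply_standardization <- function(raw, features) {
  st <- attr(features, "standardization")
  if (is.null(st)) stop("'features' lacks a standardization attribute")
  out <- raw
  for (nm in names(st$center)) {
    if (!nm %in% names(raw)) stop("missing feature column: ", nm)
    out[[nm]] <- zscore(raw[[nm]], st$center[nm], st$scale[nm])
  }
  for (base in st$interaction_bases) {
    col <- paste0(base, "_LxK")
    prod_col <- out[[paste0(base, "_L")]] * out[[paste0(base, "_K")]]
    out[[col]] <- zscore(prod_col, st$interaction_center[col],
                         st$interaction_scale[col])
  }
  out
}

# VIFs from the correlation matrix of the predictors: diag of its inverse.
vif_values <- function(x) {
  r <- stats::cor(x)
  diag(solve(r))
}

#' Collinearity screen on the continuous main predictors
#'
#' While any pair of continuous mains has |Pearson r| above `r_threshold`,
#' the member of the worst-offending pair with the larger mean absolute
#' correlation to all other mains is dropped (ties broken by canonical
#' column order: the later column goes). Survivors are then required to have
#' variance inflation factors below `vif_limit`; if not, the largest-VIF
#' column is dropped and the screen repeats. Interaction columns whose mains
#' were dropped are removed as well.
#'
#' @param features Standardized table from [assemble_features].
#' @param r_threshold Pairwise correlation cutoff (default 0.5).
#' @param vif_limit Maximum acceptable VIF (default 5).
#' @return List with `features` (reduced table, attributes updated) and
#'   `report` (data.frame: step, dropped, rule, value).
#' @export
collinearity_filter <- function(features, r_threshold = 0.5, vif_limit = 5) {
  mains <- attr(features, "continuous_mains")
  if (length(mains) < 2L) stop("need at least 2 continuous main columns")
  if (nrow(features) < 3L) stop("need at least 3 rows")
  report <- data.frame(step = integer(0), dropped = character(0),
                       rule = character(0), value = numeric(0))
  step <- 0L
  repeat {
    drop <- NULL
    if (length(mains) >= 2L) {
      r <- stats::cor(features[mains])
      diag(r) <- 0
      worst <- max(abs(r))
      if (worst > r_threshold) {
        idx <- which(abs(r) == worst, arr.ind = TRUE)[1, ]
        pair <- mains[sort(idx)]
        mean_abs <- vapply(pair, function(p) {
          mean(abs(r[p, setdiff(mains, p)]))
        }, numeric(1))
        # larger mean |r| goes; tie -> the later (second) column
        drop <- if (mean_abs[1] > mean_abs[2]) pair[1] else pair[2]
        rule <- "pairwise_r"
        value <- worst
      }
    }
    if (is.null(drop) && length(mains) >= 2L) {
      v <- vif_values(features[mains])
      if (max(v) >= vif_limit) {
        drop <- mains[which.max(v)]
        rule <- "vif"
        value <- max(v)
      }
    }
    if (is.null(drop)) break
    step <- step + 1L
    report <- rbind(report, data.frame(step = step, dropped = drop,
                                       rule = rule, value = value))
    mains <- setdiff(mains, drop)
    if (length(mains) < 2L) stop("collinearity screen left fewer than 2 predictors")
  }
  st <- attr(features, "standardization")
  # remove dropped mains and any interaction missing a surviving main
  dropped <- setdiff(attr(features, "continuous_mains"), mains)
  keep_inter <- vapply(st$interaction_bases, function(base) {
    all(paste0(base, c("_L", "_K")) %in% mains)
  }, logical(1))
  gone_inter <- paste0(st$interaction_bases[!keep_inter], "_LxK")
  out <- features[setdiff(names(features), c(dropped, gone_inter))]
  st$center <- st$center[setdiff(names(st$center), dropped)]
  st$scale <- st$scale[setdiff(names(st$scale), dropped)]
  st$interaction_bases <- st$interaction_bases[keep_inter]
  st$interaction_center <- st$interaction_center[
    setdiff(names(st$interaction_center), gone_inter)]
  st$interaction_scale <- st$interaction_scale[
    setdiff(names(st$interaction_scale), gone_inter)]
  attr(out, "standardization") <- st
  attr(out, "continuous_mains") <- mains
  attr(out, "binary") <- attr(features, "binary")
  attr(out, "excluded") <- attr(features, "excluded")
  list(features = out, report = report)
}
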