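#' Total segmented area of a print
#'
#' The number of pixels inside the segmentation mask. More visible friction
#' ridge area generally means more information available for comparison.
#'
#' @param mask Logical matrix, `TRUE` = inside the fingerprint.
#' @return Integer pixel count.
#' @export
total_area <- function(mask) {
  if (!any(mask)) stop("segmentation mask is empty")
  sum(mask)
}

#' Ratio of latent area to known-print area
#'
#' Latent area divided by known area. Not confined to \[0,1\]: a latent can
#' exceed the known print (different finger on a non-match, or smearing), so
#' the ratio is not a true proportion.
#'
#' @param latent_mask,known_mask Logical segmentation masks.
#' @return Positive real.
#' @export
area_ratio <- function(latent_mask, known_mask) {
  total_area(latent_mask) / total_area(known_mask)
}

in_mask_pixels <- function(image, mask) {
  px <- if (inherits(image, "print_image")) image$pixels else image
  if (!identical(dim(px), dim(mask))) stop("image and mask dimensions differ")
  v <- px[mask]
  if (length(v) == 0L) stop("no in-mask pixels")
  as.numeric(v)
}

#' Mean and standard deviation of pixel intensity
#'
#' Computed over all in-mask pixels; the SD is the population SD (divisor
#' n). Low mean intensity flags large dark smudges; low SD flags washed-out
#' ridge/valley transitions.
#'
#' @param image A [print_image] or intensity matrix.
#' @param mask Logical segmentation mask.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
intensity_stats <- function(image, mask) {
  v <- in_mask_pixels(image, mask)
  m <- mean(v)
  c(mean = m, sd = sqrt(mean((v - m)^2)))
}

#' Deviation from expected average intensity (DEAI)
#'
#' In an ideal print roughly half the pixels are dark ridges and half bright
#' valleys, so the expected mean intensity is 127.5. DEAI is
#' `-(|mean - 127.5|)`: always <= 0, and maximal (0) exactly when the
#' observed mean sits at the midpoint, with large deviations in either
#' direction scored equivalently.
#'
#' @inheritParams intensity_stats
#' @return Nonpositive real.
#' @export
deai <- function(image, mask) {
  -abs(mean(in_mask_pixels(image, mask)) - 127.5)
}

#' Michelson contrast
#'
#' `(Imax - Imin) / (Imax + Imin)` over in-mask pixels, in \[0,1\]. Computed
#' on pixel intensity rather than luminance, since display gamma is unknown.
#' The degenerate all-zero image is defined as contrast 0 (with a warning).
#'
#' @inheritParams intensity_stats
#' @return Value in \[0, 1\].
#' @export
michelson <- function(image, mask) {
  v <- in_mask_pixels(image, mask)
  mx <- max(v); mn <- min(v)
  if (mx == 0) {
    warning("all in-mask pixels are zero; Michelson contrast defined as 0")
    return(0)
  }
  (mx - mn) / (mx + mn)
}

#' Partition the segmented region into square blocks
#'
#' Non-overlapping `block_size` x `block_size` tiles anchored at the top-left
#' of the mask's bounding box (which makes every block statistic exactly
#' translation-invariant). A tile is retained iff at least `min_coverage` of
#' its nominal `block_size^2` pixels are in-mask, so sliver tiles at the
#' boundary cannot dominate across-block SDs.
#'
#' @param mask Logical segmentation mask.
#' @param block_size Tile side in pixels (default 50).
#' @param min_coverage Minimum in-mask fraction of a tile (default 0.5).
#' @return List of blocks, each `list(rows =, cols =, inside =)` where
#'   `inside` is the logical in-mask submask of the tile.
#' @export
block_partition <- function(mask, block_size = 50, min_coverage = 0.5) {
  if (block_size < 1) stop("block_size must be >= 1")
  if (!any(mask)) stop("segmentation mask is empty")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  blocks <- list()
  for (r0 in seq(rows[1], rows[2], by = block_size)) {
    for (c0 in seq(cols[1], cols[2], by = block_size)) {
      rr <- r0:min(r0 + block_size - 1, nrow(mask))
      cc <- c0:min(c0 + block_size - 1, ncol(mask))
      inside <- mask[rr, cc, drop = FALSE]
      if (sum(inside) / block_size^2 >= min_coverage) {
        blocks[[length(blocks) + 1L]] <- list(rows = rr, cols = cc,
                                              inside = inside)
      }
    }
  }
  if (length(blocks) == 0L) {
    stop("no block reaches ", min_coverage * 100, "% in-mask coverage")
  }
  blocks
}

block_values <- function(image, mask, block_size, f) {
  px <- if (inherits(image, "print_image")) image$pixels else image
  blocks <- block_partition(mask, block_size)
  vapply(blocks, function(b) {
    f(as.numeric(px[b$rows, b$cols][b$inside]))
  }, numeric(1))
}

#' Standard deviation of block-mean intensity
#'
#' Mean intensity per retained 50x50 block, then the (sample) SD across
#' blocks. High values flag uneven coverage -- a smudge or lighter impression
#' in part of the print -- that the global mean cannot see.
#'
#' @inheritParams intensity_stats
#' @param block_size Tile side in pixels.
#' @return SD across block means, or `NA` with a warning when fewer than two
#'   blocks are retained.
#' @export
block_intensity_sd <- function(image, mask, block_size = 50) {
  means <- block_values(image, mask, block_size, mean)
  if (length(means) < 2L) {
    warning("fewer than 2 blocks retained; block-intensity SD undefined")
    return(NA_real_)
  }
  stats::sd(means)
}

#' Block-wise Michelson contrast
#'
#' Michelson contrast within each retained 50x50 block, summarized as the
#' mean and SD across blocks. A single white and a single black pixel in an
#' otherwise uniform image give global Michelson contrast 1 but near-zero
#' block contrast, which is why the block version carries extra information:
#' high mean block contrast indicates clear ridges and valleys throughout the
#' print.
#'
#' @inheritParams block_intensity_sd
#' @return Named vector `c(mean = , sd = )`; `sd` is `NA` (with a warning)
#'   when fewer than two blocks are retained.
#' @export
block_contrast <- function(image, mask, block_size = 50) {
  con <- block_values(image, mask, block_size, function(v) {
    mx <- max(v); mn <- min(v)
    if (mx == 0) 0 else (mx - mn) / (mx + mn)
  })
  s <- if (length(con) < 2L) {
    warning("fewer than 2 blocks retained; block-contrast SD undefined")
    NA_real_
  } else {
    stats::sd(con)
  }
  c(mean = mean(con), sd = s)
}

#' Euclidean sum of latent and known ridge reliability
#'
#' `sqrt(rL^2 + rK^2)`: large when both prints have a high proportion of
#' regions with well-defined ridge orientation.
#'
#' @param r_latent,r_known Ridge-reliability proportions in \[0,1\].
#' @return Nonnegative real (at most `sqrt(2)`).
#' @export
ridge_sum <- function(r_latent, r_known) {
  stopifnot(r_latent >= 0, r_latent <= 1, r_known >= 0, r_known <= 1)
  sqrt(r_latent^2 + r_known^2)
}
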