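#' Construct a print image
#'
#' A print image is an 8-bit grayscale raster with dark ridges: intensity 0 is
#' ridge ink, 255 is bright background. Polarity is never auto-inverted.
#'
#' @param pixels Integer matrix of intensities in \[0, 255\], indexed
#'   (row, col), 0-based coordinates are used nowhere in the API -- R's
#'   1-based matrix indexing applies throughout.
#' @param role One of `"latent"` or `"known"`.
#' @param id Character identifier for the print.
#' @return An object of class `print_image`: a list with elements `pixels`,
#'   `role`, `id`.
#' @export
print_image <- function(pixels, role = c("latent", "known"), id = "print") {
  role <- match.arg(role)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("print image must have height and width >= 1")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("print image intensities must lie in [0, 255]")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, role = role, id = as.character(id)),
            class = "print_image")
}

#' @export
print.print_image <- function(x, ...) {
  cat(sprintf("<print_image '%s' (%s), %d x %d, intensity [%d, %d]>\n",
              x$id, x$role, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Read a PNG/TIFF into a [0,1] numeric matrix, averaging channels if needed.
read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(arr)) == 3L) {
    # color or alpha channels: average the first three (or fewer) channels
    nc <- min(dim(arr)[3], 3L)
    arr <- apply(arr[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  arr
}

#' Read a fingerprint image and its segmentation mask
#'
#' Both readers return values scaled to \[0,1\]; intensities are mapped
#' linearly onto 0-255 and rounded, which is the identity on 8-bit input and
#' maps the maximum representable value of deeper inputs (e.g. 16-bit TIFF)
#' to 255. The mask is a raster of the same dimensions; any nonzero pixel is
#' inside the fingerprint region.
#'
#' @param image_path Path to an 8- or 16-bit grayscale PNG or TIFF.
#' @param mask_path Path to a mask PNG/TIFF of identical dimensions.
#' @param role `"latent"` or `"known"`.
#' @param id Print identifier; defaults to the image file name.
#' @return A list with elements `image` (a [print_image]) and `mask`
#'   (logical matrix, `TRUE` = inside the print).
#' @export
read_print <- function(image_path, mask_path, role = c("latent", "known"),
                       id = NULL) {
  role <- match.arg(role)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(image_path))
  img <- round(read_raster(image_path) * 255)
  msk <- read_raster(mask_path) > 0
  if (!identical(dim(img), dim(msk))) {
    stop(sprintf("print '%s': image is %dx%d but mask is %dx%d",
                 id, nrow(img), ncol(img), nrow(msk), ncol(msk)))
  }
  if (!any(msk)) stop(sprintf("print '%s': segmentation mask is empty", id))
  list(image = print_image(img, role = role, id = id), mask = msk)
}

#' Write a print image or mask as 8-bit PNG
#'
#' @param x A [print_image] or a logical/0-255 integer matrix.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_print <- function(x, path) {
  px <- if (inherits(x, "print_image")) x$pixels else as.matrix(x)
  if (is.logical(px)) px <- px * 255L
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Read per-image global-feature annotations
#'
#' Annotations record the Level I landmarks an examiner (or the synthetic
#' generator) marked: whether a core and/or delta is visible and, when a core
#' is present, its pattern class.
#'
#' @param path CSV with columns `id, role, core_present, delta_present,
#'   core_type` (core_type empty when no core).
#' @return A data.frame with logical `core_present`/`delta_present`.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "role", "core_present", "delta_present", "core_type")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols)) {
    stop("annotation file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ann$core_present <- as.logical(ann$core_present)
  ann$delta_present <- as.logical(ann$delta_present)
  bad <- !ann$core_present & !is.na(ann$core_type) & nzchar(ann$core_type)
  if (any(bad)) {
    stop("core_type set while core_present is FALSE for: ",
         paste(ann$id[bad], collapse = ", "))
  }
  ann
}

trial_columns <- c("pair_id", "expert_id", "is_match", "judged_match",
                   "difficulty", "confidence", "response_time", "timed_out")

#' Read an examiner trial table, applying the decision-based exclusion rule
#'
#' One row per (print pair, examiner) presentation. A trial on which the
#' examiner never registered a match/non-match decision (`judged_match`
#' missing) is excluded; a trial with a decision but missing difficulty or
#' confidence ratings is retained with the ratings absent. Counts of both are
#' reported via `message()`. Correctness is recomputed as
#' `judged_match == is_match`, never trusted from the file.
#'
#' @param path CSV with header exactly `pair_id, expert_id, is_match,
#'   judged_match, difficulty, confidence, response_time, timed_out`.
#' @return A data.frame with the columns above plus `correct` (0/1), one row
#'   per retained trial.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    warning("trial file is empty: ", path)
    out <- raw
    out$correct <- integer(0)
    return(out)
  }
  missing_cols <- setdiff(trial_columns, names(raw))
  if (length(missing_cols)) {
    stop("trial file lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("is_match", "judged_match", "timed_out")) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  clean_trials(raw)
}

#' Apply the trial-exclusion rule to an in-memory table
#'
#' @param trials Data.frame with the trial columns (see [read_trials]).
#' @return The retained rows with a recomputed `correct` column.
#' @export
clean_trials <- function(trials) {
  dup <- duplicated(trials[c("pair_id", "expert_id")])
  if (any(dup)) {
    stop("duplicate (pair_id, expert_id) rows: ",
         paste(unique(paste(trials$pair_id[dup], trials$expert_id[dup],
                            sep = "/")), collapse = ", "))
  }
  no_decision <- is.na(trials$judged_match)
  kept <- trials[!no_decision, , drop = FALSE]
  missing_ratings <- is.na(kept$difficulty) | is.na(kept$confidence)
  message(sprintf(
    "trials: %d read, %d excluded (no comparison decision), %d retained (%d without ratings)",
    nrow(trials), sum(no_decision), nrow(kept), sum(missing_ratings)))
  kept$correct <- as.integer(kept$judged_match == kept$is_match)
  rownames(kept) <- NULL
  kept
}

#' Write a trial table as CSV
#'
#' @param trials Trial data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[intersect(c(trial_columns, "correct"),
                                    names(trials))],
                   path, row.names = FALSE)
  invisible(path)
}
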