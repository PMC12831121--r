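#' Read a raster-scan TIFF series
#'
#' Reads a single- or multi-page grayscale TIFF (one page per raster scan)
#' into a [frame_series()]. Integer TIFFs are read at their native values
#' (not rescaled to `[0, 1]`); RGB / multi-channel TIFFs are rejected.
#'
#' @param path TIFF file path.
#' @param pixel_scale micrometres per pixel of the acquisition.
#' @return a [frame_series()].
#' @export
read_frames <- function(path, pixel_scale = DEFAULT_PIXEL_SCALE) {
  if (!file.exists(path))
    abort_microseg(sprintf("input file does not exist: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  raw_pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(raw_pages)) raw_pages <- list(raw_pages)
  frames <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (length(dim(p)) != 2L)
      abort_microseg(sprintf(
        "unsupported TIFF layout in %s: expected single-channel grayscale pages",
        path))
    bits <- attr(p, "bits.per.sample")
    ## 8/16-bit pages are integer data: take native counts; 32-bit pages are
    ## float samples, already at their stored values
    p <- if (!is.null(bits) && bits < 32L) raw_pages[[i]] else p
    p <- unclass(p)
    attributes(p) <- list(dim = dim(p))
    storage.mode(p) <- "double"
    p
  })
  frame_series(frames, pixel_scale = pixel_scale)
}

#' Write an intensity image as 32-bit float TIFF
#'
#' TIFF float storage here is confined to `[0, 1]`, so images with a larger
#' range are divided by their maximum before writing; the applied divisor is
#' returned (1 for already-normalized images) and recorded in the pipeline
#' manifest so absolute intensities remain recoverable.
#'
#' @param image an [intensity_image()] or matrix.
#' @param path output path.
#' @return invisibly, the scale divisor applied before writing.
#' @export
write_image <- function(image, path) {
  v <- as_image_values(image)
  scale <- max(v, 1)
  tiff::writeTIFF(pmin(pmax(v / scale, 0), 1), path, bits.per.sample = 32L)
  invisible(scale)
}

#' Read/write a 16-bit label image
#'
#' Label images (background 0, cells 1..N) round-trip exactly through
#' 16-bit TIFF; more than 65535 cells is rejected.
#'
#' @param labels integer matrix of instance labels.
#' @param path TIFF path.
#' @return `write_labels`: invisibly, the path; `read_labels`: the integer
#'   label matrix.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535L)
    abort_microseg("more than 65535 labels cannot be stored in 16-bit TIFF")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) != 2L)
    abort_microseg("label TIFF must be single-channel")
  matrix(as.integer(round(v * 65535)), nrow(v), ncol(v))
}

#' Flatten a proposal set into a label image
#'
#' Cells are painted in ascending proposal order with labels 1..N; where
#' residual overlaps exist (pairwise IoU below the NMS threshold can still
#' be non-zero) the higher-scoring, earlier proposal wins.
#'
#' @param proposals a [proposal_set()].
#' @return an integer label matrix.
#' @export
proposals_to_labels <- function(proposals) {
  labels <- matrix(0L, proposals$image_shape[1L], proposals$image_shape[2L])
  for (i in rev(seq_len(length(proposals))))
    labels[proposals$masks[[i]]] <- i
  labels
}

#' Write / read a proposal archive
#'
#' A proposal set is stored as two files: a multi-page binary TIFF (one page
#' per mask, foreground 1) and a CSV of scores (`index, score, source`), so
#' any backend's output is interchangeable with any consumer.
#'
#' @param proposals a [proposal_set()].
#' @param masks_path multi-page TIFF path for the mask stack.
#' @param scores_path CSV path for the score table.
#' @return `write_proposals`: invisibly, `masks_path`; `read_proposals`: the
#'   reconstructed [proposal_set()].
#' @export
write_proposals <- function(proposals, masks_path, scores_path) {
  if (length(proposals) == 0L)
    abort_microseg("cannot write an empty proposal archive as TIFF")
  tiff::writeTIFF(lapply(proposals$masks, function(m) (m != 0) * 1),
                  masks_path, bits.per.sample = 8L)
  utils::write.csv(
    data.frame(index = seq_len(length(proposals)), score = proposals$scores,
               source = proposals$source),
    scores_path, row.names = FALSE)
  invisible(masks_path)
}

#' @rdname write_proposals
#' @export
read_proposals <- function(masks_path, scores_path) {
  pages <- tiff::readTIFF(masks_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  masks <- lapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      abort_microseg("proposal mask TIFF must be single-channel")
    matrix(p > 0.5, nrow(p), ncol(p))
  })
  sc <- utils::read.csv(scores_path)
  proposal_set(masks, sc$score, source = as.character(sc$source[1L]))
}

#' Write a feature table as CSV
#'
#' @param features the data frame from [extract_features()].
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read point annotations from CSV
#'
#' Expects columns `row` and `col` (0-based pixel coordinates), optionally
#' preceded by an `image` column for multi-image files, in which case a list
#' of annotation sets (one per image) is returned.
#'
#' @param path CSV path.
#' @param image_shape integer `c(H, W)` of the annotated image(s).
#' @return an [annotation_set()], or a named list of them when an `image`
#'   column is present.
#' @export
read_annotations <- function(path, image_shape) {
  tab <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(tab)))
    abort_microseg("annotation CSV must have 'row' and 'col' columns")
  if ("image" %in% names(tab)) {
    split_tab <- split(tab, tab$image)
    lapply(split_tab, function(t)
      annotation_set(t[, c("row", "col")], image_shape))
  } else {
    annotation_set(tab[, c("row", "col")], image_shape)
  }
}
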