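#' Default pixel scale of the acquisition geometry
#'
#' A 256 x 256 pixel field of view covering 20 x 20 micrometres gives
#' 20/256 = 0.078125 um per pixel.
#' @export
DEFAULT_PIXEL_SCALE <- 20 / 256

#' Construct a frame series
#'
#' A frame series holds the T raster scans acquired over one field of view:
#' an ordered set of 2-D intensity grids of identical size, plus the physical
#' pixel scale. Fast raster scanning yields low photon counts per scan, so a
#' single frame is shot-noise dominated; downstream, [stack_frames()] averages
#' the frames to recover signal-to-noise.
#'
#' @param frames a list of numeric matrices, or a 3-D array with the frame
#'   index last (`H x W x T`). All frames must share the same dimensions and
#'   contain only non-negative finite values.
#' @param pixel_scale physical pixel size in micrometres per pixel.
#' @return an object of class `frame_series` with elements `frames`
#'   (list of matrices) and `pixel_scale`.
#' @seealso [stack_frames()], [read_frames()]
#' @export
frame_series <- function(frames, pixel_scale = DEFAULT_PIXEL_SCALE) {
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[3L]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) < 1L)
    abort_shape("'frames' must be a non-empty list of matrices (T >= 1)")
  if (!all(vapply(frames, is.matrix, logical(1L))))
    abort_shape("every frame must be a 2-D matrix")
  dims <- vapply(frames, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    abort_shape("all frames must share identical dimensions")
  vals <- unlist(frames, use.names = FALSE)
  if (any(!is.finite(vals)) || any(vals < 0))
    abort_microseg("frame intensities must be finite and non-negative")
  structure(
    list(frames = lapply(frames, function(f) {
      storage.mode(f) <- "double"
      f
    }), pixel_scale = as.numeric(pixel_scale)),
    class = "frame_series"
  )
}

#' @export
print.frame_series <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_series> T = %d frames of %d x %d px, %.6g um/px\n",
              length(x$frames), d[1L], d[2L], x$pixel_scale))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

#' Construct an intensity image
#'
#' A single 2-D intensity grid plus its pixel scale and a flag recording
#' whether the values have been rescaled to `[0, 1]` (required before
#' denoising and intensity-ratio filtering, whose parameters live on the
#' unit scale).
#'
#' @param values numeric matrix of intensities.
#' @param pixel_scale micrometres per pixel.
#' @param normalized logical; `TRUE` asserts values lie in `[0, 1]`.
#' @return an object of class `intensity_image`.
#' @export
intensity_image <- function(values, pixel_scale = DEFAULT_PIXEL_SCALE,
                            normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L)
    abort_shape("'values' must be a non-empty numeric matrix")
  if (any(!is.finite(values)))
    abort_microseg("image intensities must be finite")
  if (isTRUE(normalized) && (min(values) < 0 || max(values) > 1))
    abort_microseg("normalized = TRUE but values fall outside [0, 1]")
  storage.mode(values) <- "double"
  structure(
    list(values = values, pixel_scale = as.numeric(pixel_scale),
         normalized = isTRUE(normalized)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %d x %d px, %.6g um/px, range [%.4g, %.4g]%s\n",
    nrow(x$values), ncol(x$values), x$pixel_scale,
    min(x$values), max(x$values),
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$values)

as_image_values <- function(image) {
  if (inherits(image, "intensity_image")) image$values
  else if (is.matrix(image)) image
  else abort_shape("expected an intensity_image or a matrix")
}

#' Average raster scans into one stacked image
#'
#' Computes the per-pixel arithmetic mean over the T frames of a series.
#' Averaging T independent scans reduces the per-pixel noise variance by a
#' factor of T, which is the first and cheapest denoising step for
#' photon-starved fast-scanning acquisitions.
#'
#' @param series a [frame_series()].
#' @return an [intensity_image()] with `normalized = FALSE` and the series'
#'   pixel scale. Averaging is done in double precision regardless of the
#'   input TIFF bit depth.
#' @examples
#' fs <- frame_series(list(matrix(0:3, 2), matrix(4:7, 2)), pixel_scale = 1)
#' stack_frames(fs)$values
#' @export
stack_frames <- function(series) {
  if (!inherits(series, "frame_series"))
    series <- frame_series(series)
  avg <- Reduce(`+`, series$frames) / length(series$frames)
  intensity_image(avg, pixel_scale = series$pixel_scale, normalized = FALSE)
}

#' Min-max normalize an image to [0, 1]
#'
#' Rescales intensities affinely so the minimum maps to 0 and the maximum to
#' 1. Pixel rank order is preserved. Downstream steps (denoising with a
#' unit-scale sigma, multi-Otsu intensity filtering) require normalized
#' input.
#'
#' @param image an [intensity_image()] or matrix.
#' @return a normalized [intensity_image()].
#' @export
normalize_image <- function(image) {
  v <- as_image_values(image)
  scale <- if (inherits(image, "intensity_image")) image$pixel_scale
           else DEFAULT_PIXEL_SCALE
  rng <- range(v)
  if (rng[1L] == rng[2L])
    abort_microseg("cannot normalize a constant image (zero intensity range)")
  intensity_image((v - rng[1L]) / (rng[2L] - rng[1L]),
                  pixel_scale = scale, normalized = TRUE)
}

#' Clamp image intensities to a fraction of the maximum
#'
#' Replaces every value v by `min(v, fraction * max(image))`. Clamping a
#' bright-nucleus image to, say, 20% of its maximum reveals dim structures
#' (e.g. membranes) that would otherwise be crushed by display/normalization
#' against the brightest pixels. No rescaling is performed afterwards; call
#' [normalize_image()] explicitly if a unit range is needed.
#'
#' @param image an [intensity_image()] or matrix.
#' @param fraction clamp level as a fraction of the image maximum, in (0, 1].
#' @return an [intensity_image()] with the same pixel scale. The `normalized`
#'   flag is preserved (clamping cannot push values outside `[0, 1]`).
#' @export
clamp_image <- function(image, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    abort_microseg("'fraction' must be a single number in (0, 1]")
  v <- as_image_values(image)
  out <- pmin(v, fraction * max(v))
  scale <- if (inherits(image, "intensity_image")) image$pixel_scale
           else DEFAULT_PIXEL_SCALE
  norm <- inherits(image, "intensity_image") && image$normalized
  intensity_image(out, pixel_scale = scale, normalized = norm)
}
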