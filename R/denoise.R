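## Denoising sits behind a small registry so the algorithm is a contract
## (values in [0,1] + noise sigma -> values), not a hard dependency:
## the built-in "nlm" denoiser is always available, and an external BM3D
## implementation can be plugged in under the name "bm3d".

#' Register a denoiser implementation
#'
#' A denoiser is a function `f(values, sigma, ...)` mapping a numeric matrix
#' with values in `[0, 1]` and a noise standard deviation (on the same unit
#' scale) to a denoised matrix of identical dimensions. Registering under the
#' name `"bm3d"` plugs an external BM3D implementation into the standard
#' pipeline position.
#'
#' @param name denoiser name (string).
#' @param fn function of `(values, sigma, ...)` returning a matrix.
#' @export
register_denoiser <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .microseg_registry[[paste0("denoiser_", name)]] <- fn
  invisible(name)
}

get_denoiser <- function(name) {
  fn <- .microseg_registry[[paste0("denoiser_", name)]]
  if (is.null(fn)) {
    if (name == "bm3d")
      abort_dependency(paste0(
        "no BM3D implementation is registered; use the built-in ",
        "method = \"nlm\" or register one with register_denoiser(\"bm3d\", fn)"))
    abort_microseg(sprintf("unknown denoiser '%s'", name))
  }
  fn
}

#' Denoise a normalized intensity image
#'
#' Applies the selected denoiser to an image on the `[0, 1]` scale. The
#' default method is a fast non-local-means filter (see
#' [nlm_denoise()]); an external BM3D implementation registered via
#' [register_denoiser()] is selected with `method = "bm3d"`.
#'
#' @param image a normalized [intensity_image()] (see [normalize_image()]).
#' @param sigma noise standard deviation on the `[0, 1]` intensity scale;
#'   default 0.2, matched to the low-photon-count regime of fast raster
#'   scanning.
#' @param method denoiser name; `"nlm"` is built in.
#' @param ... passed through to the denoiser.
#' @return a denoised [intensity_image()] of identical dimensions and pixel
#'   scale, still flagged normalized (output is clipped to `[0, 1]`).
#' @export
denoise_image <- function(image, sigma = 0.2, method = "nlm", ...) {
  if (!inherits(image, "intensity_image") || !image$normalized)
    abort_microseg(
      "denoise_image() requires a normalized image: sigma lives on the [0, 1] scale")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    abort_microseg("'sigma' must be a single positive number")
  fn <- get_denoiser(method)
  out <- fn(image$values, sigma, ...)
  if (!is.matrix(out) || !all(dim(out) == dim(image$values)))
    abort_shape("denoiser violated its contract: output shape differs from input")
  out <- pmin(pmax(out, 0), 1)
  intensity_image(out, pixel_scale = image$pixel_scale, normalized = TRUE)
}

## Replicate-padding shift: value at (r, c) becomes value at (r - dr, c - dc),
## clamped to the image border.
shift_replicate <- function(v, dr, dc) {
  h <- nrow(v); w <- ncol(v)
  v[pmin(pmax(seq_len(h) - dr, 1L), h), pmin(pmax(seq_len(w) - dc, 1L), w),
    drop = FALSE]
}

## Mean filter over a (2r+1)^2 box with replicate padding, via an integral
## image - O(HW) per call independent of r.
box_mean <- function(m, r) {
  if (r == 0L) return(m)
  h <- nrow(m); w <- ncol(m)
  p <- m[pmin(pmax(seq_len(h + 2L * r) - r, 1L), h),
         pmin(pmax(seq_len(w + 2L * r) - r, 1L), w), drop = FALSE]
  ii <- apply(p, 2L, cumsum)
  ii <- t(apply(ii, 1L, cumsum))
  ii <- rbind(0, cbind(0, ii))
  k <- 2L * r + 1L
  ri <- seq_len(h); ci <- seq_len(w)
  (ii[ri + k, ci + k, drop = FALSE] - ii[ri, ci + k, drop = FALSE] -
     ii[ri + k, ci, drop = FALSE] + ii[ri, ci, drop = FALSE]) / (k * k)
}

#' Fast non-local-means denoising
#'
#' Patch-based averaging: each pixel is replaced by a weighted mean of pixels
#' in a search window, weighted by the similarity of their surrounding
#' patches. Implemented with the shifted-image formulation (one squared
#' difference plus one box filter per window offset), which is exact and fast
#' in vectorized form. Patch distances are noise-compensated by subtracting
#' `2 * sigma^2` before exponentiation, so pure noise differences do not
#' suppress averaging.
#'
#' @param values numeric matrix with values in `[0, 1]`.
#' @param sigma noise standard deviation on the `[0, 1]` scale.
#' @param patch_radius patch half-size in pixels (patch is
#'   `(2*patch_radius+1)^2`).
#' @param search_radius search-window half-size in pixels.
#' @param h filtering bandwidth; defaults to `0.6 * sigma`.
#' @return the denoised matrix, same dimensions as `values`.
#' @export
nlm_denoise <- function(values, sigma, patch_radius = 2L, search_radius = 5L,
                        h = 0.6 * sigma) {
  acc <- matrix(0, nrow(values), ncol(values))
  wsum <- acc
  comp <- 2 * sigma^2
  for (dr in -search_radius:search_radius) {
    for (dc in -search_radius:search_radius) {
      s <- shift_replicate(values, dr, dc)
      d2 <- box_mean((values - s)^2, patch_radius)
      w <- exp(-pmax(d2 - comp, 0) / (h * h))
      acc <- acc + w * s
      wsum <- wsum + w
    }
  }
  acc / wsum
}

register_denoiser("nlm", function(values, sigma, ...) {
  nlm_denoise(values, sigma, ...)
})
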