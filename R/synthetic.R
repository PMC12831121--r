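#' Specification of a synthetic field of view
#'
#' Defines the acquisition geometry and the population of rod-shaped cells
#' to simulate. Defaults reproduce the reference acquisition: a 256 x 256 px
#' field covering 20 x 20 um (0.078125 um/px) imaged over 7 raster scans,
#' with photon shot noise (Poisson) on the expected per-pixel photon count
#' and additive Gaussian dark noise. Cell sizes default to an E. coli-like
#' population (length 2-4 um, width 0.6-1.0 um).
#'
#' @param image_size field side in pixels.
#' @param fov_um physical field side in micrometres.
#' @param n_frames number of raster scans T.
#' @param n_cells number of cells to place.
#' @param length_range,width_range uniform sampling ranges for rod length
#'   and width in um; the shortest length must be at least the largest width
#'   (rods, not disks).
#' @param cell_intensity expected photons per cell pixel per frame.
#' @param background_intensity expected photons per background pixel per
#'   frame.
#' @param dark_noise_sd standard deviation of the additive Gaussian dark
#'   noise, in intensity units per frame.
#' @param margin_px placement margin: no cell footprint may come within this
#'   many pixels of the border (keeps ground truth clear of the
#'   edge-exclusion band of the post-processing chain).
#' @param min_separation_px minimum gap between cells in pixels, enforced by
#'   dilating each candidate footprint before the overlap test.
#' @param seed integer RNG seed; the scene is fully reproducible from it.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 256L, fov_um = 20, n_frames = 7L,
                       n_cells = 50L, length_range = c(2, 4),
                       width_range = c(0.6, 1.0), cell_intensity = 20,
                       background_intensity = 2, dark_noise_sd = 1,
                       margin_px = 4L, min_separation_px = 2L, seed = 1L) {
  if (n_cells < 0L) abort_microseg("'n_cells' must be >= 0")
  if (n_frames < 1L) abort_microseg("'n_frames' must be >= 1")
  if (length_range[1L] < width_range[2L])
    abort_microseg(
      "rod geometry requires min(length_range) >= max(width_range)")
  if (cell_intensity < 0 || background_intensity < 0 || dark_noise_sd < 0)
    abort_microseg("intensities and noise levels must be non-negative")
  structure(
    list(image_size = as.integer(image_size), fov_um = fov_um,
         n_frames = as.integer(n_frames), n_cells = as.integer(n_cells),
         length_range = length_range, width_range = width_range,
         cell_intensity = cell_intensity,
         background_intensity = background_intensity,
         dark_noise_sd = dark_noise_sd, margin_px = as.integer(margin_px),
         min_separation_px = as.integer(min_separation_px),
         seed = as.integer(seed),
         pixel_scale = fov_um / image_size),
    class = "scene_spec"
  )
}

#' Rasterize a spherocylinder footprint
#'
#' The 2-D cross-section of a rod: all pixels whose centre lies within
#' `W/2` of the central segment of length `L - W` (two semicircular caps
#' joined by a rectangle). Exact rasterization by point-to-segment distance.
#'
#' @param center numeric `c(row, col)` centre in pixel coordinates
#'   (continuous, 1-based pixel grid).
#' @param angle orientation of the long axis in radians (from the column
#'   axis); the footprint is invariant under `angle + pi`.
#' @param length_um,width_um rod length and width in um, `L >= W > 0`.
#' @param pixel_scale micrometres per pixel.
#' @param image_size field side in pixels.
#' @return a logical `image_size x image_size` mask.
#' @export
render_rod <- function(center, angle, length_um, width_um,
                       pixel_scale = DEFAULT_PIXEL_SCALE,
                       image_size = 256L) {
  if (width_um <= 0 || length_um < width_um)
    abort_microseg("render_rod() requires L >= W > 0")
  L <- length_um / pixel_scale
  W <- width_um / pixel_scale
  half <- (L - W) / 2
  dx <- cos(angle); dy <- sin(angle)   # (x, y) = (col, row)
  cx <- center[2L]; cy <- center[1L]
  ex <- c(cx - half * dx, cx + half * dx)
  ey <- c(cy - half * dy, cy + half * dy)
  r <- W / 2
  if (min(ex) - r < 0 || max(ex) + r > image_size ||
      min(ey) - r < 0 || max(ey) + r > image_size)
    abort_microseg("rod footprint exceeds the image bounds")
  ## evaluate only the bounding window
  c0 <- max(1L, floor(min(ex) - r)); c1 <- min(image_size, ceiling(max(ex) + r) + 1L)
  r0 <- max(1L, floor(min(ey) - r)); r1 <- min(image_size, ceiling(max(ey) + r) + 1L)
  cols <- c0:c1; rows <- r0:r1
  px <- matrix(rep(cols - 0.5, each = length(rows)), length(rows))
  py <- matrix(rep(rows - 0.5, times = length(cols)), length(rows))
  ## distance from pixel centre to the central segment
  vx <- px - ex[1L]; vy <- py - ey[1L]
  seg_len2 <- (ex[2L] - ex[1L])^2 + (ey[2L] - ey[1L])^2
  t <- if (seg_len2 > 0)
    pmin(pmax((vx * (ex[2L] - ex[1L]) + vy * (ey[2L] - ey[1L])) / seg_len2, 0), 1)
  else 0
  qx <- ex[1L] + t * (ex[2L] - ex[1L])
  qy <- ey[1L] + t * (ey[2L] - ey[1L])
  inside <- (px - qx)^2 + (py - qy)^2 <= r^2
  mask <- matrix(FALSE, image_size, image_size)
  mask[rows, cols] <- inside
  if (!any(mask)) abort_microseg("rod footprint rasterized to zero pixels")
  mask
}

#' Generate a seeded synthetic scene
#'
#' Places `n_cells` non-overlapping rods by rejection sampling (uniform
#' centre, orientation, length and width within the spec's ranges; a
#' candidate is rejected when its footprint, dilated by the minimum
#' separation, touches an already-placed cell), then simulates each raster
#' scan as an independent Poisson draw of the expected per-pixel photon
#' count (cell vs background) plus Gaussian dark noise, clipped at zero.
#' Fully reproducible from `spec$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `synthetic_scene`: a list with `frames`
#'   (a [frame_series()]), `truth_labels` (integer label matrix, background
#'   0), `truth_params` (data frame: cell, row, col, angle, length_um,
#'   width_um), `annotations` (an [annotation_set()] of cell centres) and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  if (!inherits(spec, "scene_spec")) abort_microseg("'spec' must be a scene_spec")
  size <- spec$image_size
  mean_area_px <- with(spec, {
    Lm <- mean(length_range) / pixel_scale
    Wm <- mean(width_range) / pixel_scale
    pi * (Wm / 2)^2 + Wm * (Lm - Wm)
  })
  if (spec$n_cells * mean_area_px > 0.4 * size^2)
    abort_microseg(paste0(
      "requested density exceeds the 40% area limit for non-overlapping ",
      "placement; reduce n_cells or cell sizes"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  occupied <- matrix(FALSE, size, size)
  labels <- matrix(0L, size, size)
  params <- vector("list", spec$n_cells)
  sep_kern <- if (spec$min_separation_px > 0L)
    EBImage::makeBrush(2L * spec$min_separation_px + 1L, "disc") else NULL
  placed <- 0L
  for (i in seq_len(spec$n_cells)) {
    ok <- FALSE
    for (try in seq_len(400L)) {
      L <- stats::runif(1L, spec$length_range[1L], spec$length_range[2L])
      W <- stats::runif(1L, spec$width_range[1L], spec$width_range[2L])
      ang <- stats::runif(1L, 0, pi)
      reach <- L / spec$pixel_scale / 2 + 1
      lo <- spec$margin_px + reach
      hi <- size - spec$margin_px - reach
      if (hi <= lo) next
      ctr <- stats::runif(2L, lo, hi)
      m <- tryCatch(
        render_rod(ctr, ang, L, W, spec$pixel_scale, size),
        microseg_error = function(e) NULL)
      if (is.null(m)) next
      test <- if (is.null(sep_kern)) m else {
        out <- EBImage::dilate(matrix(as.numeric(m), size, size), sep_kern)
        matrix(out > 0.5, size, size)
      }
      if (any(test & occupied)) next
      occupied <- occupied | test
      labels[m] <- i
      params[[i]] <- data.frame(cell = i, row = ctr[1L], col = ctr[2L],
                                angle = ang, length_um = L, width_um = W)
      ok <- TRUE
      placed <- placed + 1L
      break
    }
    if (!ok)
      abort_microseg(sprintf(
        "could not place cell %d without overlap after 400 attempts; the field is too dense", i))
  }
  truth_params <- if (placed > 0L) do.call(rbind, params) else
    data.frame(cell = integer(0), row = numeric(0), col = numeric(0),
               angle = numeric(0), length_um = numeric(0),
               width_um = numeric(0))
  lambda <- matrix(spec$background_intensity, size, size)
  lambda[labels > 0L] <- spec$background_intensity + spec$cell_intensity
  frames <- lapply(seq_len(spec$n_frames), function(t) {
    f <- matrix(stats::rpois(size * size, lambda), size, size) +
      matrix(stats::rnorm(size * size, 0, spec$dark_noise_sd), size, size)
    pmax(f, 0)
  })
  ann_pts <- if (placed > 0L)
    cbind(row = floor(truth_params$row), col = floor(truth_params$col))
  else matrix(numeric(0), 0L, 2L)
  structure(
    list(frames = frame_series(frames, pixel_scale = spec$pixel_scale),
         truth_labels = labels, truth_params = truth_params,
         annotations = annotation_set(ann_pts, c(size, size)),
         spec = spec),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scene> %d cells, %d frames of %d x %d px (seed %d)\n",
    max(x$truth_labels), length(x$frames$frames), x$spec$image_size,
    x$spec$image_size, x$spec$seed))
  invisible(x)
}
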