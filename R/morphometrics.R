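#' Mean intensity of a mask on the stacked image
#'
#' Overlays the mask on the stacked (raw-scale, not normalized or denoised)
#' image and averages the pixel values under it — the per-cell intensity
#' feature, in the acquisition's own intensity units.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param stacked the stacked [intensity_image()] (or a matrix).
#' @return the arithmetic mean intensity under the mask.
#' @export
mean_intensity <- function(mask, stacked) {
  v <- as_image_values(stacked)
  mask <- mask != 0
  if (!all(dim(mask) == dim(v)))
    abort_shape("mask and image dimensions differ")
  if (!any(mask)) abort_microseg("mean_intensity() of an empty mask")
  mean(v[mask])
}

## Corner-point cloud of a binary mask: each foreground pixel (r, c)
## contributes its four corners, so a w x h pixel block has exact extents
## w x h (pixel-centre hulls would lose one pixel per side).
mask_corner_points <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort_microseg("mask has no foreground pixels")
  r <- idx[, 1L]; c <- idx[, 2L]
  pts <- rbind(cbind(c - 1, r - 1), cbind(c, r - 1),
               cbind(c - 1, r), cbind(c, r))  # (x, y) = (col, row)
  unique(pts)
}

#' Minimum-area rotated enclosing rectangle of a mask
#'
#' Rotating-calipers search over the convex hull of the mask's pixel-corner
#' points: the minimum-area enclosing rectangle has a side collinear with a
#' hull edge, so it suffices to test one orientation per edge. This is the
#' computable realization of "the bounding box with maximum overlap" used to
#' measure rod length.
#'
#' @param mask logical matrix.
#' @return a list with `center` (x, y in px), `angle` (radians of the long
#'   side from the x/column axis, in `[0, pi)`), `length_px` (longer side),
#'   `width_px` (shorter side).
#' @export
min_area_rect <- function(mask) {
  pts <- mask_corner_points(mask)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) abort_microseg("degenerate mask: convex hull is not 2-D")
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len                 # along the edge
    v <- c(-u[2L], u[1L])        # perpendicular
    pu <- hp %*% u
    pv <- hp %*% v
    du <- max(pu) - min(pu)
    dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      cu <- (max(pu) + min(pu)) / 2
      cv <- (max(pv) + min(pv)) / 2
      best <- list(area = area, u = u, v = v, du = du, dv = dv,
                   center = cu * u + cv * v)
    }
  }
  if (is.null(best)) abort_microseg("degenerate mask geometry")
  if (best$du >= best$dv) {
    long <- best$du; short <- best$dv; axis <- best$u
  } else {
    long <- best$dv; short <- best$du; axis <- best$v
  }
  ang <- atan2(axis[2L], axis[1L]) %% pi
  list(center = as.numeric(best$center), angle = ang,
       length_px = long, width_px = short)
}

#' Fit a rod (spherocylinder cross-section) to a mask
#'
#' Length is the longer side of the minimum-area rotated enclosing rectangle.
#' Width is refined to represent the cell body rather than the caps: the box
#' is divided into four equal sections along its length, and the mean extent
#' of the mask perpendicular to the major axis is averaged over 1-px axial
#' bins falling in the middle two sections.
#'
#' @param mask logical matrix, area >= 5 px.
#' @param pixel_scale micrometres per pixel.
#' @return a list with `length_um`, `width_um` (guaranteed
#'   `width_um <= length_um`) and `box` (the fitted rectangle from
#'   [min_area_rect()]).
#' @export
fit_rod <- function(mask, pixel_scale = DEFAULT_PIXEL_SCALE) {
  mask <- mask != 0
  if (sum(mask) < 5)
    abort_microseg("fit_rod() needs a mask of at least 5 px")
  box <- min_area_rect(mask)
  L_px <- box$length_px
  axis <- c(cos(box$angle), sin(box$angle))
  perp <- c(-axis[2L], axis[1L])
  idx <- which(mask, arr.ind = TRUE)
  ctr <- cbind(idx[, 2L] - 0.5, idx[, 1L] - 0.5)  # pixel centres (x, y)
  u <- as.vector(ctr %*% axis)
  v <- as.vector(ctr %*% perp)
  u <- u - (min(u) - 0.5)  # axial position in [0, ~L_px]
  mid <- u >= L_px / 4 & u <= 3 * L_px / 4
  if (!any(mid)) mid <- rep(TRUE, length(u))  # very short masks: use all
  bins <- floor(u[mid])
  widths <- tapply(v[mid], bins, function(z) max(z) - min(z) + 1)
  W_px <- mean(widths)
  L <- L_px * pixel_scale
  W <- min(W_px * pixel_scale, L)
  list(length_um = L, width_um = W, box = box)
}

#' Spherocylinder volume of a rod-shaped cell
#'
#' Models the cell as a cylinder of length `L - W` capped by two hemispheres
#' of diameter `W`:
#' `V = pi (W/2)^2 (L - W) + (4/3) pi (W/2)^3`.
#' At `L = W` the model reduces to a sphere of diameter `W`.
#'
#' @param length_um cell length L in micrometres (tip to tip).
#' @param width_um cell width W in micrometres; must satisfy `W <= L`.
#' @return volume in femtolitres (1 um^3 = 1 fL).
#' @examples
#' rod_volume(3.215, 0.865)  # 1.720 fL
#' @export
rod_volume <- function(length_um, width_um) {
  if (any(width_um <= 0) || any(length_um < width_um))
    abort_microseg("rod_volume() requires L >= W > 0")
  r <- width_um / 2
  pi * r^2 * (length_um - width_um) + 4 / 3 * pi * r^3
}

#' Equivalent-sphere radius of a round mask
#'
#' The radius of the circle with the same area as the mask:
#' `r = sqrt(area_px / pi) * pixel_scale`. Used to size approximately round
#' objects (e.g. yeast nuclei) for the sphere volume model.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param pixel_scale micrometres per pixel.
#' @return radius in micrometres.
#' @export
fit_sphere <- function(mask, pixel_scale = DEFAULT_PIXEL_SCALE) {
  mask <- mask != 0
  a <- sum(mask)
  if (a == 0) abort_microseg("fit_sphere() of an empty mask")
  sqrt(a / pi) * pixel_scale
}

#' Sphere volume
#'
#' `V = (4/3) pi r^3`, in femtolitres.
#'
#' @param radius_um radius in micrometres, positive.
#' @return volume in fL.
#' @examples
#' sphere_volume(1.014)  # 4.367 fL
#' @export
sphere_volume <- function(radius_um) {
  if (any(radius_um <= 0)) abort_microseg("sphere_volume() requires r > 0")
  4 / 3 * pi * radius_um^3
}

#' Extract per-cell features from refined masks
#'
#' One row per mask: geometry under the chosen model (rod: length, width,
#' spherocylinder volume; sphere: equivalent radius, sphere volume), area in
#' pixels, and mean intensity measured on the stacked image. A geometry
#' failure on one mask is recorded in that row's `error` column and does not
#' abort the extraction. When `pixel_scale` is `NA`, geometric features are
#' reported in pixels and volumes are omitted.
#'
#' @param masks a [proposal_set()] or list of logical matrices (normally the
#'   output of [run_postprocess()]).
#' @param stacked the stacked [intensity_image()] on the raw intensity scale.
#' @param model `"rod"` or `"sphere"`.
#' @param pixel_scale micrometres per pixel; default taken from `stacked`.
#' @return a data frame with columns `cell_id`, `model`, `area_px`,
#'   `mean_intensity`, `L_um`, `W_um`, `r_um`, `volume_fL`, `error`.
#' @export
extract_features <- function(masks, stacked, model = c("rod", "sphere"),
                             pixel_scale = NULL) {
  model <- match.arg(model)
  mlist <- if (inherits(masks, "proposal_set")) masks$masks else masks
  if (is.null(pixel_scale))
    pixel_scale <- if (inherits(stacked, "intensity_image"))
      stacked$pixel_scale else DEFAULT_PIXEL_SCALE
  in_px <- is.na(pixel_scale)
  scale <- if (in_px) 1 else pixel_scale
  rows <- lapply(seq_along(mlist), function(i) {
    m <- mlist[[i]] != 0
    out <- data.frame(cell_id = i, model = model, area_px = sum(m),
                      mean_intensity = NA_real_, L_um = NA_real_,
                      W_um = NA_real_, r_um = NA_real_,
                      volume_fL = NA_real_, error = NA_character_)
    tryCatch({
      out$mean_intensity <- mean_intensity(m, stacked)
      if (model == "rod") {
        fit <- fit_rod(m, scale)
        out$L_um <- fit$length_um
        out$W_um <- fit$width_um
        if (!in_px) out$volume_fL <- rod_volume(fit$length_um, fit$width_um)
      } else {
        r <- fit_sphere(m, scale)
        out$r_um <- r
        if (!in_px) out$volume_fL <- sphere_volume(r)
      }
    }, microseg_error = function(e) out$error <<- conditionMessage(e))
    out
  })
  out <- do.call(rbind, c(list(data.frame(
    cell_id = integer(0), model = character(0), area_px = numeric(0),
    mean_intensity = numeric(0), L_um = numeric(0), W_um = numeric(0),
    r_um = numeric(0), volume_fL = numeric(0), error = character(0))), rows))
  rownames(out) <- NULL
  out
}
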