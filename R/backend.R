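#' Construct a set of mask proposals
#'
#' A proposal set is an ordered collection of candidate instance masks over
#' one image, each with a predicted-quality score in `[0, 1]` (for
#' prompt-based foundation-model backends this is the predicted IoU of the
#' mask; for the thresholding baseline it is the component's mean intensity).
#'
#' @param masks list of logical matrices, all of identical dimensions, each
#'   with at least one foreground pixel.
#' @param scores numeric vector of the same length, values in `[0, 1]`.
#' @param image_shape integer `c(H, W)`; defaults to the masks' dimensions.
#' @param source backend identifier string.
#' @return an object of class `proposal_set`.
#' @export
proposal_set <- function(masks, scores = numeric(0), image_shape = NULL,
                         source = "unknown") {
  if (!is.list(masks)) abort_shape("'masks' must be a list of logical matrices")
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) abort_shape("each mask must be a matrix")
    m <- m != 0
    if (!any(m)) abort_microseg("a mask proposal must have >= 1 foreground pixel")
    m
  })
  if (length(masks) > 0L) {
    dims <- vapply(masks, dim, integer(2L))
    if (any(dims != dims[, 1L]))
      abort_shape("all masks must share the same image shape")
    if (is.null(image_shape)) image_shape <- dims[, 1L]
    if (!all(dims[, 1L] == image_shape))
      abort_shape("mask dimensions disagree with 'image_shape'")
  }
  if (is.null(image_shape))
    abort_shape("'image_shape' is required for an empty proposal set")
  if (length(scores) != length(masks))
    abort_microseg("'scores' must have one entry per mask")
  if (length(scores) && (any(scores < 0) || any(scores > 1)))
    abort_microseg("scores must lie in [0, 1]")
  structure(
    list(masks = masks, scores = as.numeric(scores),
         image_shape = as.integer(image_shape), source = source),
    class = "proposal_set"
  )
}

#' @export
length.proposal_set <- function(x) length(x$masks)

#' @export
print.proposal_set <- function(x, ...) {
  cat(sprintf("<proposal_set> %d proposals on %d x %d px (source: %s)\n",
              length(x$masks), x$image_shape[1L], x$image_shape[2L], x$source))
  invisible(x)
}

subset_proposals <- function(ps, keep) {
  proposal_set(ps$masks[keep], ps$scores[keep],
               image_shape = ps$image_shape, source = ps$source)
}

#' Regular point-prompt grid
#'
#' The n x n grid of point prompts used to query a prompt-based segmentation
#' backend: points are evenly spaced with half-cell offsets, point i (0-based)
#' sitting at `(i + 0.5) / n` of the side length, so the grid is symmetric
#' under reflection about the image centre and no point touches the border.
#'
#' @param height,width image size in pixels.
#' @param n points per side (default 32, i.e. 1024 prompts).
#' @return a data frame with columns `x` (along width) and `y` (along
#'   height), n^2 rows in row-major order.
#' @examples
#' head(point_grid(256, 256, 32))  # first point (4, 4), spacing 8
#' @export
point_grid <- function(height, width, n = 32L) {
  if (n < 1L) abort_microseg("'n' must be >= 1")
  if (height < n || width < n)
    abort_microseg("grid size 'n' exceeds an image side")
  xs <- (seq_len(n) - 0.5) * width / n
  ys <- (seq_len(n) - 0.5) * height / n
  data.frame(x = rep(xs, times = n), y = rep(ys, each = n))
}

## 8-connected labeling. EBImage::bwlabel() is 4-connected, so diagonal-only
## neighbours come back as distinct labels; merge them with a union-find pass
## over the two diagonal offsets.
label_components8 <- function(bw) {
  bw <- bw != 0
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(round(lab)), nrow(bw), ncol(bw))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  h <- nrow(lab); w <- ncol(lab)
  diag_pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),  # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))   # down-left
  )
  diag_pairs <- diag_pairs[diag_pairs[, 1L] > 0L & diag_pairs[, 2L] > 0L &
                             diag_pairs[, 1L] != diag_pairs[, 2L], , drop = FALSE]
  if (nrow(diag_pairs)) {
    diag_pairs <- unique(diag_pairs)
    for (k in seq_len(nrow(diag_pairs)))
      unite(diag_pairs[k, 1L], diag_pairs[k, 2L])
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  out
}

#' Deterministic thresholding baseline backend
#'
#' Proposes one mask per 8-connected component of the super-threshold pixels
#' of a normalized image, scored by the component's mean intensity (already
#' in `[0, 1]`). Deterministic, dependency-free, and with graded scores, it
#' serves both as a test backend and as a reasonable segmenter for
#' well-separated bright cells on dark background.
#'
#' @param image a normalized [intensity_image()].
#' @param threshold foreground threshold in `[0, 1)`.
#' @return a [proposal_set()] ordered by descending score; ties are broken by
#'   the first foreground pixel in row-major order so the ordering is
#'   reproducible.
#' @export
baseline_propose <- function(image, threshold = 0.5) {
  if (!inherits(image, "intensity_image") || !image$normalized)
    abort_microseg("baseline_propose() requires a normalized image")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    abort_microseg("'threshold' must lie in [0, 1)")
  v <- image$values
  lab <- label_components8(v > threshold)
  n <- max(lab)
  if (n == 0L)
    return(proposal_set(list(), numeric(0), image_shape = dim(v),
                        source = "baseline"))
  masks <- lapply(seq_len(n), function(i) lab == i)
  scores <- vapply(masks, function(m) mean(v[m]), numeric(1L))
  ## row-major index of first foreground pixel, for reproducible tie-breaks
  first_px <- vapply(masks, function(m) {
    idx <- which(m)
    rr <- (idx - 1L) %% nrow(m)
    cc <- (idx - 1L) %/% nrow(m)
    min(rr * ncol(m) + cc)
  }, numeric(1L))
  ord <- order(-scores, first_px)
  proposal_set(masks[ord], scores[ord], image_shape = dim(v),
               source = "baseline")
}

#' Register a segmentation backend
#'
#' A backend is a function `f(image, ...)` returning a [proposal_set()].
#' The baseline thresholding backend is pre-registered as `"baseline"`; an
#' adapter for an external prompt-based model can be registered as `"sam"`
#' (see [sam_backend_stub()]).
#'
#' @param name backend name.
#' @param fn function of `(image, ...)` returning a `proposal_set`.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .microseg_registry[[paste0("backend_", name)]] <- fn
  invisible(name)
}

get_backend <- function(name) {
  fn <- .microseg_registry[[paste0("backend_", name)]]
  if (is.null(fn)) abort_microseg(sprintf("unknown backend '%s'", name))
  fn
}

#' Generate mask proposals via a registered backend
#'
#' @param image a normalized [intensity_image()].
#' @param backend backend name (`"baseline"` built in, `"sam"` adapter stub,
#'   or any name registered with [register_backend()]).
#' @param ... passed to the backend (e.g. `threshold` for the baseline,
#'   `weights` for an external adapter).
#' @return a [proposal_set()].
#' @export
propose <- function(image, backend = "baseline", ...) {
  fn <- get_backend(backend)
  ps <- fn(image, ...)
  if (!inherits(ps, "proposal_set"))
    abort_shape(sprintf("backend '%s' did not return a proposal_set", backend))
  ps
}

#' Adapter seam for an external prompt-based segmentation model
#'
#' The package does not ship or run a foundation-model segmenter; this stub
#' defines the adapter contract. Calling it without a configured weights path
#' raises a dependency error (class `microseg_dependency_error`) rather than
#' failing silently. A real adapter should generate masks from the
#' [point_grid()] prompts and map each mask's predicted IoU into the
#' `proposal_set` score; any further generator settings are passed through
#' untouched.
#'
#' @param image a normalized [intensity_image()].
#' @param weights path to model weights (required).
#' @param grid_n prompt-grid side (default 32).
#' @param ... pass-through generator settings.
#' @export
sam_backend_stub <- function(image, weights = NULL, grid_n = 32L, ...) {
  if (is.null(weights))
    abort_dependency(
      "the 'sam' backend needs external model weights: pass weights = <path>")
  abort_dependency(paste0(
    "no external segmentation runtime is linked into this installation; ",
    "register a real adapter with register_backend(\"sam\", fn) that runs ",
    "the model on the ", grid_n, "x", grid_n, " point-prompt grid"))
}

register_backend("baseline", function(image, ...) baseline_propose(image, ...))
register_backend("sam", sam_backend_stub)
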