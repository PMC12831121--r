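#' Construct a point-annotation set
#'
#' Manually marked cell locations for one image, used as detection ground
#' truth: one (row, col) point per cell, 0-based pixel coordinates.
#'
#' @param points a 2-column matrix or data frame of (row, col) coordinates.
#' @param image_shape integer `c(H, W)`.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(points, image_shape) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 2L)
  if (ncol(points) != 2L)
    abort_shape("'points' must have two columns (row, col)")
  image_shape <- as.integer(image_shape)
  if (nrow(points) > 0L &&
      (any(points < 0) || any(points[, 1L] >= image_shape[1L]) ||
       any(points[, 2L] >= image_shape[2L])))
    abort_microseg("annotation points must lie inside the image")
  colnames(points) <- c("row", "col")
  structure(list(points = points, image_shape = image_shape),
            class = "annotation_set")
}

#' @export
length.annotation_set <- function(x) nrow(x$points)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d points on %d x %d px\n",
              nrow(x$points), x$image_shape[1L], x$image_shape[2L]))
  invisible(x)
}

#' Match detected masks against point annotations
#'
#' A mask detects an annotation when the annotated point lies inside the
#' mask. The assignment is one-to-one: a mask containing several candidate
#' points keeps the one nearest to its centroid, and surplus points count as
#' missed. Masks left without an annotation are incorrect detections
#' ("wrong position"); annotations left without a mask are missed cells.
#' The error rate is `(missed + incorrect) / n_annotations` — it has no
#' upper cap, since spurious masks can outnumber cells.
#'
#' @param masks a [proposal_set()] (typically post-refinement).
#' @param annotations an [annotation_set()] with at least one point.
#' @return an object of class `match_result`: a list with `pairs` (matrix of
#'   annotation index, mask index), `missed` (annotation indices),
#'   `incorrect` (mask indices), `n_annotations`, and `error_rate`.
#' @export
match_detections <- function(masks, annotations) {
  n_ann <- length(annotations)
  if (n_ann < 1L)
    abort_microseg("error rate is undefined for an empty annotation set")
  if (!all(masks$image_shape == annotations$image_shape))
    abort_shape("masks and annotations disagree on image shape")
  pts <- annotations$points
  assigned <- rep(FALSE, n_ann)
  pairs <- matrix(integer(0), 0L, 2L,
                  dimnames = list(NULL, c("annotation", "mask")))
  incorrect <- integer(0)
  for (mi in seq_len(length(masks))) {
    m <- masks$masks[[mi]]
    inside <- which(!assigned &
                      m[cbind(pts[, 1L] + 1L, pts[, 2L] + 1L)])
    if (length(inside) == 0L) {
      incorrect <- c(incorrect, mi)
      next
    }
    idx <- which(m, arr.ind = TRUE)
    ctr <- c(mean(idx[, 1L]) - 1, mean(idx[, 2L]) - 1)  # 0-based centroid
    d2 <- (pts[inside, 1L] - ctr[1L])^2 + (pts[inside, 2L] - ctr[2L])^2
    pick <- inside[which.min(d2)]
    assigned[pick] <- TRUE
    pairs <- rbind(pairs, c(pick, mi))
  }
  missed <- which(!assigned)
  structure(
    list(pairs = pairs, missed = missed, incorrect = incorrect,
         n_annotations = n_ann,
         error_rate = (length(missed) + length(incorrect)) / n_ann),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d/%d matched, %d missed, %d incorrect; error rate %.1f%%\n",
    nrow(x$pairs), x$n_annotations, length(x$missed), length(x$incorrect),
    100 * x$error_rate))
  invisible(x)
}

#' Per-image error-rate summary table
#'
#' One row per image with its annotated cell count and detection error rate
#' in percent, closed by an `Average` row holding the unweighted mean of the
#' per-image rates (and the total cell count).
#'
#' @param results a list of [match_detections()] results, optionally named
#'   by image.
#' @return a data frame with columns `image`, `n_cells`, `error_rate_pct`.
#' @export
error_table <- function(results) {
  if (length(results) < 1L) abort_microseg("need at least one image result")
  if (inherits(results, "match_result")) results <- list(results)
  nm <- names(results)
  if (is.null(nm)) nm <- as.character(seq_along(results))
  rates <- vapply(results, function(r) r$error_rate, numeric(1L))
  ns <- vapply(results, function(r) r$n_annotations, numeric(1L))
  out <- data.frame(image = nm, n_cells = ns, error_rate_pct = 100 * rates)
  rbind(out, data.frame(image = "Average", n_cells = sum(ns),
                        error_rate_pct = mean(100 * rates)))
}
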