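#' Post-processing filter configuration
#'
#' Collects every threshold of the mask-refinement chain. Defaults follow the
#' settings used for rod-shaped bacteria in dense low-contrast fields:
#' masks below 10 px are noise; masks above `(shorter side / 4)^2` px are
#' merged objects or background; a mask's mean intensity must lie within
#' `[r1 * mu_1, r2 * mu_K]` where `mu_1 < ... < mu_K` are the K multi-Otsu
#' class means of the whole normalized image; overlapping masks with IoU
#' above 0.3 are reduced to the highest-confidence one; masks touching the
#' first or last `edge_margin` rows/columns are dropped as truncated; finally
#' each mask is smoothed by morphological closing with a disk of radius
#' `closing_radius`.
#'
#' @param min_area minimum mask area in px^2 (masks strictly smaller are
#'   removed).
#' @param max_area maximum mask area in px^2, or `NULL` to use the
#'   `(shorter image side / 4)^2` rule (masks strictly larger are removed).
#' @param r1,r2 lower/upper intensity-ratio factors of the mean-intensity
#'   band.
#' @param K number of multi-Otsu intensity classes (>= 2); pick according to
#'   the expected contrast structure of the image.
#' @param iou_threshold pairwise IoU above which two masks are considered
#'   duplicates, in (0, 1).
#' @param edge_margin width in px of the boundary band that no retained mask
#'   may touch; 2 excludes the first/last two rows and columns.
#' @param closing_radius radius in px of the disk structuring element used
#'   for closing.
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(min_area = 10, max_area = NULL, r1 = 1.3, r2 = 1.3,
                          K = 3L, iou_threshold = 0.3, edge_margin = 2L,
                          closing_radius = 1L) {
  if (min_area < 1) abort_microseg("'min_area' must be >= 1")
  if (!is.null(max_area) && max_area < min_area)
    abort_microseg("'max_area' must be >= 'min_area'")
  if (r1 <= 0 || r2 <= 0) abort_microseg("'r1' and 'r2' must be positive")
  if (K < 2L) abort_microseg("'K' must be >= 2")
  if (iou_threshold <= 0 || iou_threshold >= 1)
    abort_microseg("'iou_threshold' must lie in (0, 1)")
  if (edge_margin < 0) abort_microseg("'edge_margin' must be >= 0")
  if (closing_radius < 0) abort_microseg("'closing_radius' must be >= 0")
  structure(
    list(min_area = min_area, max_area = max_area, r1 = r1, r2 = r2,
         K = as.integer(K), iou_threshold = iou_threshold,
         edge_margin = as.integer(edge_margin),
         closing_radius = as.integer(closing_radius)),
    class = "filter_config"
  )
}

empty_report <- function() {
  data.frame(index = integer(0), stage = character(0), diagnostic = numeric(0))
}

report_rows <- function(index, stage, diagnostic) {
  data.frame(index = as.integer(index),
             stage = rep_len(stage, length(index)),
             diagnostic = as.numeric(diagnostic))
}

resolve_max_area <- function(config, image_shape) {
  if (!is.null(config$max_area)) config$max_area
  else (min(image_shape) / 4)^2
}

#' Filter proposals by mask area
#'
#' Removes masks strictly smaller than `min_area` px (noise specks) and
#' strictly larger than the maximum-area rule (merged objects / background).
#' Masks exactly at either bound are retained.
#'
#' @param proposals a [proposal_set()].
#' @param config a [filter_config()].
#' @return a list with `proposals` (the retained set) and `report` (one row
#'   per removal: original index, stage `area_small` or `area_large`, and the
#'   offending area as diagnostic).
#' @export
filter_area <- function(proposals, config = filter_config()) {
  areas <- vapply(proposals$masks, sum, numeric(1L))
  amax <- resolve_max_area(config, proposals$image_shape)
  small <- areas < config$min_area
  large <- areas > amax
  keep <- !small & !large
  rep <- rbind(report_rows(which(small), "area_small", areas[small]),
               report_rows(which(large), "area_large", areas[large]))
  list(proposals = subset_proposals(proposals, keep),
       report = if (nrow(rep)) rep[order(rep$index), ] else empty_report(),
       keep = which(keep))
}

#' Multi-Otsu histogram partition
#'
#' Partitions the intensity histogram into K classes by maximizing the
#' between-class variance, the K-class generalization of Otsu's threshold.
#' Solved exactly by dynamic programming over a fixed-bin histogram
#' (O(K * nbins^2)), so any K is handled without combinatorial search.
#' Class means are the means of the actual pixel values assigned to each
#' class, not bin centres.
#'
#' @param values numeric vector or matrix of intensities.
#' @param K number of classes (>= 2).
#' @param nbins histogram resolution.
#' @return a list with `thresholds` (K-1 ascending class boundaries),
#'   `class_means` (K ascending means), and `counts` (pixels per class).
#' @export
multi_otsu <- function(values, K = 3L, nbins = 256L) {
  x <- as.numeric(values)
  K <- as.integer(K)
  if (K < 2L) abort_microseg("'K' must be >= 2")
  if (length(unique(x)) < K)
    abort_microseg(sprintf(
      "multi-Otsu with K = %d needs at least K distinct intensity values", K))
  lo <- min(x); hi <- max(x)
  bin <- pmin(floor((x - lo) / (hi - lo) * nbins) + 1L, nbins)
  cnt <- tabulate(bin, nbins)
  sm <- as.vector(rowsum(x, bin, reorder = TRUE))
  sm_full <- numeric(nbins)
  sm_full[sort(unique(bin))] <- sm
  W <- cumsum(cnt)
  S <- cumsum(sm_full)
  ## f[k, b]: best sum of class w*mu^2 splitting bins 1..b into k classes
  f <- matrix(-Inf, K, nbins)
  arg <- matrix(NA_integer_, K, nbins)
  f[1L, ] <- ifelse(W > 0, S^2 / W, -Inf)
  for (k in 2:K) {
    for (b in k:nbins) {
      t <- (k - 1L):(b - 1L)
      dw <- W[b] - W[t]
      val <- f[k - 1L, t] + ifelse(dw > 0, (S[b] - S[t])^2 / dw, -Inf)
      j <- which.max(val)
      f[k, b] <- val[j]
      arg[k, b] <- t[j]
    }
  }
  if (!is.finite(f[K, nbins]))
    abort_microseg("multi-Otsu failed: histogram cannot support K non-empty classes")
  cuts <- integer(K - 1L)
  b <- nbins
  for (k in K:2) {
    cuts[k - 1L] <- arg[k, b]
    b <- arg[k, b]
  }
  thresholds <- lo + cuts * (hi - lo) / nbins
  ## assign classes by histogram bin so boundaries are exact bin edges
  cls <- findInterval(bin, cuts + 0.5) + 1L
  class_means <- as.vector(tapply(x, cls, mean))
  counts <- as.vector(table(cls))
  list(thresholds = thresholds, class_means = class_means, counts = counts)
}

#' Filter proposals by mean intensity
#'
#' The whole normalized image is partitioned into K multi-Otsu classes with
#' means `mu_1 < ... < mu_K` (dark to bright). A mask is retained only when
#' its mean intensity lies in the inclusive band
#' `r1 * mu_1 <= mean <= r2 * mu_K`: masks darker than the band are
#' background gaps mis-segmented as objects, brighter ones are saturated
#' artifacts.
#'
#' @param proposals a [proposal_set()].
#' @param image the normalized [intensity_image()] the proposals live on.
#' @param config a [filter_config()].
#' @return a list with `proposals`, `report` (stages `intensity_low` /
#'   `intensity_high`, diagnostic = the mask's mean intensity), `keep`, and
#'   `class_means` (the K multi-Otsu means used).
#' @export
filter_intensity <- function(proposals, image, config = filter_config()) {
  if (!inherits(image, "intensity_image") || !image$normalized)
    abort_microseg("filter_intensity() requires the normalized image")
  if (!all(dim(image$values) == proposals$image_shape))
    abort_shape("image shape disagrees with the proposal set")
  mu <- multi_otsu(image$values, K = config$K)$class_means
  lo <- config$r1 * mu[1L]
  hi <- config$r2 * mu[length(mu)]
  means <- vapply(proposals$masks, function(m) mean(image$values[m]),
                  numeric(1L))
  low <- means < lo
  high <- means > hi
  keep <- !low & !high
  rep <- rbind(report_rows(which(low), "intensity_low", means[low]),
               report_rows(which(high), "intensity_high", means[high]))
  list(proposals = subset_proposals(proposals, keep),
       report = if (nrow(rep)) rep[order(rep$index), ] else empty_report(),
       keep = which(keep), class_means = mu)
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b logical matrices of identical dimensions; at least one must be
#'   non-empty.
#' @return `|a & b| / |a | b|` in `[0, 1]`; symmetric in its arguments.
#' @export
mask_iou <- function(a, b) {
  a <- a != 0; b <- b != 0
  if (!all(dim(a) == dim(b))) abort_shape("masks must share dimensions")
  u <- sum(a | b)
  if (u == 0) abort_microseg("IoU of two empty masks is undefined")
  sum(a & b) / u
}

mask_bbox <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  c(min(idx[, 1L]), max(idx[, 1L]), min(idx[, 2L]), max(idx[, 2L]))
}

bbox_overlap <- function(a, b) {
  a[1L] <= b[2L] && b[1L] <= a[2L] && a[3L] <= b[4L] && b[3L] <= a[4L]
}

#' Confidence-guided non-maximum suppression
#'
#' Greedy NMS over the proposal set: proposals are visited in descending
#' score order and kept unless their IoU with an already-kept proposal
#' exceeds `iou_threshold`; among any conflicting pair the higher-score mask
#' survives. Comparisons are made against kept masks only, so a suppressed
#' mask cannot veto a later one. The retained set has pairwise IoU at or
#' below the threshold.
#'
#' @param proposals a [proposal_set()] with scores.
#' @param config a [filter_config()].
#' @return a list with `proposals`, `report` (stage `nms`, diagnostic = the
#'   IoU with the kept mask that suppressed it), and `keep`.
#' @export
suppress_overlaps <- function(proposals, config = filter_config()) {
  n <- length(proposals)
  if (n == 0L)
    return(list(proposals = proposals, report = empty_report(),
                keep = integer(0)))
  ord <- order(-proposals$scores, seq_len(n))
  bboxes <- lapply(proposals$masks, mask_bbox)
  kept <- integer(0)
  removed <- integer(0)
  diag <- numeric(0)
  for (i in ord) {
    hit <- NA_real_
    for (j in kept) {
      if (!bbox_overlap(bboxes[[i]], bboxes[[j]])) next
      v <- mask_iou(proposals$masks[[i]], proposals$masks[[j]])
      if (v > config$iou_threshold) { hit <- v; break }
    }
    if (is.na(hit)) kept <- c(kept, i)
    else { removed <- c(removed, i); diag <- c(diag, hit) }
  }
  kept <- sort(kept)
  rep <- if (length(removed))
    report_rows(removed, "nms", diag)[order(removed), ] else empty_report()
  list(proposals = subset_proposals(proposals, kept), report = rep,
       keep = kept)
}

#' Remove masks touching the image boundary
#'
#' A mask with any foreground pixel in the first or last `edge_margin` rows
#' or columns likely belongs to a cell truncated by the field of view and is
#' removed, since its measured size and intensity would be biased low.
#'
#' @param proposals a [proposal_set()].
#' @param config a [filter_config()]; `edge_margin = 2` removes masks
#'   touching the first/last two rows/columns.
#' @return a list with `proposals`, `report` (stage `edge`, diagnostic = the
#'   0-based offending row or column index), and `keep`.
#' @export
remove_edge_masks <- function(proposals, config = filter_config()) {
  h <- proposals$image_shape[1L]; w <- proposals$image_shape[2L]
  m <- config$edge_margin
  if (m == 0L || length(proposals) == 0L)
    return(list(proposals = proposals, report = empty_report(),
                keep = seq_len(length(proposals))))
  offending <- vapply(proposals$masks, function(mk) {
    idx <- which(mk, arr.ind = TRUE)
    r <- idx[, 1L]; c <- idx[, 2L]
    bad_r <- r <= m | r > h - m
    bad_c <- c <= m | c > w - m
    if (!any(bad_r | bad_c)) return(NA_real_)
    k <- which(bad_r | bad_c)[1L]
    if (bad_r[k]) r[k] - 1 else c[k] - 1  # 0-based coordinate
  }, numeric(1L))
  keep <- is.na(offending)
  rep <- if (any(!keep))
    report_rows(which(!keep), "edge", offending[!keep]) else empty_report()
  list(proposals = subset_proposals(proposals, keep), report = rep,
       keep = which(keep))
}

closing_kernel <- function(radius) {
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

#' Morphological closing of each mask
#'
#' Dilation followed by erosion with a disk structuring element, applied to
#' each mask independently (never to a fused label image, so closing cannot
#' merge neighbouring cells). Closing smooths jagged contours and fills
#' small interior gaps; the result always contains the input foreground.
#'
#' @param proposals a [proposal_set()].
#' @param config a [filter_config()]; `closing_radius = 0` is a no-op.
#' @return the closed [proposal_set()] (scores preserved).
#' @export
close_masks <- function(proposals, config = filter_config()) {
  if (config$closing_radius == 0L || length(proposals) == 0L)
    return(proposals)
  kern <- closing_kernel(config$closing_radius)
  pad <- 2L * config$closing_radius
  closed <- lapply(proposals$masks, function(m) {
    ## pad so the result is the closing on an unbounded canvas (restricted
    ## to the image), independent of any boundary convention
    h <- nrow(m); w <- ncol(m)
    big <- matrix(0, h + 2L * pad, w + 2L * pad)
    big[pad + seq_len(h), pad + seq_len(w)] <- as.numeric(m)
    out <- EBImage::closing(big, kern)
    matrix(out[pad + seq_len(h), pad + seq_len(w)] > 0.5, h, w)
  })
  proposal_set(closed, proposals$scores, image_shape = proposals$image_shape,
               source = proposals$source)
}

#' Run the full mask-refinement chain
#'
#' Applies, in order: area filtering, mean-intensity filtering,
#' confidence-guided NMS, edge-mask removal, and per-mask morphological
#' closing. Each stage can be toggled off (e.g. sparse fields where
#' overlapping nucleus+membrane masks should both survive disable `"nms"`).
#' Area and intensity bounds are enforced on the pre-closing masks; closing
#' is cosmetic smoothing applied last.
#'
#' @param proposals a [proposal_set()].
#' @param image the normalized [intensity_image()]; required when the
#'   `"intensity"` stage is enabled.
#' @param config a [filter_config()].
#' @param stages character vector choosing the stages to run, a subset of
#'   `c("area", "intensity", "nms", "edge", "closing")`; order of execution
#'   is fixed regardless of the order given.
#' @return an object of class `postprocess_result`: a list with
#'   `proposals` (retained, closed masks), `report` (one row per removed
#'   input proposal: original index, stage, diagnostic; together with the
#'   retained indices this partitions the input set), `keep` (original
#'   indices of retained proposals) and `class_means` (multi-Otsu means, if
#'   the intensity stage ran).
#' @export
run_postprocess <- function(proposals, image = NULL, config = filter_config(),
                            stages = c("area", "intensity", "nms", "edge",
                                       "closing")) {
  all_stages <- c("area", "intensity", "nms", "edge", "closing")
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    abort_microseg(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  ps <- proposals
  orig <- seq_len(length(proposals))
  report <- empty_report()
  class_means <- NULL
  run_stage <- function(res) {
    report <<- rbind(report,
                     within(res$report, index <- orig[index]))
    orig <<- orig[res$keep]
    res$proposals
  }
  if ("area" %in% stages) ps <- run_stage(filter_area(ps, config))
  if ("intensity" %in% stages) {
    if (is.null(image))
      abort_microseg("the intensity stage requires 'image'")
    res <- filter_intensity(ps, image, config)
    class_means <- res$class_means
    ps <- run_stage(res)
  }
  if ("nms" %in% stages) ps <- run_stage(suppress_overlaps(ps, config))
  if ("edge" %in% stages) ps <- run_stage(remove_edge_masks(ps, config))
  if ("closing" %in% stages) ps <- close_masks(ps, config)
  structure(
    list(proposals = ps, report = report, keep = orig,
         class_means = class_means),
    class = "postprocess_result"
  )
}

#' @export
print.postprocess_result <- function(x, ...) {
  cat(sprintf("<postprocess_result> %d retained, %d removed\n",
              length(x$proposals), nrow(x$report)))
  if (nrow(x$report))
    print(table(x$report$stage))
  invisible(x)
}
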