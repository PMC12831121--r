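# Shared fixtures and independent brute-force oracles. Oracles here are
# deliberately naive (loops, flood fill, exhaustive search) so they stay
# independent of the package's vectorized/DP implementations.

# Brute-force 8-connected labeling by flood fill.
flood_label8 <- function(bw) {
  bw <- bw != 0
  h <- nrow(bw); w <- ncol(bw)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!bw[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1L && r <= h && c >= 1L && c <= w &&
            bw[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Brute-force binary dilation/erosion with an explicit structuring element.
brute_dilate <- function(m, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L; kc <- (ncol(kern) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
      if (kern[i, j] == 0) next
      rr <- r + i - 1L - kr; cc <- c + j - 1L - kc
      if (rr >= 1L && rr <= h && cc >= 1L && cc <= w && m[rr, cc]) {
        out[r, c] <- TRUE
      }
    }
  }
  out
}

brute_erode <- function(m, kern) {
  kr <- (nrow(kern) - 1L) %/% 2L; kc <- (ncol(kern) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(TRUE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    for (i in seq_len(nrow(kern))) for (j in seq_len(ncol(kern))) {
      if (kern[i, j] == 0) next
      rr <- r + i - 1L - kr; cc <- c + j - 1L - kc
      inside <- rr >= 1L && rr <= h && cc >= 1L && cc <= w
      if (!inside || !m[rr, cc]) out[r, c] <- FALSE
    }
  }
  out
}

# Closing on an unbounded canvas: pad far enough that the image boundary
# cannot influence the cropped result.
brute_close <- function(m, kern) {
  pad <- max(nrow(kern), ncol(kern))
  h <- nrow(m); w <- ncol(m)
  big <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  big[pad + seq_len(h), pad + seq_len(w)] <- m
  out <- brute_erode(brute_dilate(big, kern), kern)
  out[pad + seq_len(h), pad + seq_len(w)]
}

# Rectangular block mask helper.
block_mask <- function(shape, rows, cols) {
  m <- matrix(FALSE, shape[1L], shape[2L])
  m[rows, cols] <- TRUE
  m
}

# Rasterized rotated solid rectangle (pixel-centre test), for rod fitting.
rotated_rect_mask <- function(shape, center, angle, len, wid) {
  rr <- matrix(rep(seq_len(shape[1L]) - 0.5, shape[2L]), shape[1L])
  cc <- matrix(rep(seq_len(shape[2L]) - 0.5, each = shape[1L]), shape[1L])
  u <- (cc - center[2L]) * cos(angle) + (rr - center[1L]) * sin(angle)
  v <- -(cc - center[2L]) * sin(angle) + (rr - center[1L]) * cos(angle)
  abs(u) <= len / 2 & abs(v) <= wid / 2
}

# The six-proposal refinement fixture: a 5-px speck, a full-image mask, a
# duplicate pair sitting against the border (its NMS winner then falls to
# the edge stage), an edge-touching mask and one valid interior cell, over a
# 64 x 64 three-level intensity image. Only the valid cell survives the
# whole chain.
make_refinement_fixture <- function() {
  shape <- c(64L, 64L)
  img <- matrix(0.02, shape[1L], shape[2L])
  img[50:55, 10:55] <- 0.4                     # mid-gray band (3rd class)
  img[25:32, 30:49] <- 0.8                     # valid cell region
  img[1:6, 40:45] <- 0.8                       # duplicate-pair region
  img[1:6, 20:25] <- 0.8                       # edge region
  image <- intensity_image(img, pixel_scale = 1, normalized = TRUE)
  speck <- block_mask(shape, 35, 8:12)                   # 5 px
  full <- block_mask(shape, 1:64, 1:64)                  # 4096 px > 256
  dup_a <- block_mask(shape, 1:6, 40:45)                 # 36 px, score 0.9
  dup_b <- dup_a                                         # score 0.8
  edge <- block_mask(shape, 1:6, 20:25)                  # touches row 1
  valid <- block_mask(shape, 25:32, 30:49)               # 160 px interior
  ps <- proposal_set(list(speck, full, dup_a, dup_b, edge, valid),
                     scores = c(0.5, 0.6, 0.9, 0.8, 0.7, 0.95),
                     image_shape = shape)
  list(image = image, proposals = ps,
       idx = list(speck = 1L, full = 2L, dup_a = 3L, dup_b = 4L,
                  edge = 5L, valid = 6L))
}

# Random proposal sets of axis-aligned blocks for NMS property tests.
random_block_proposals <- function(shape = c(32L, 32L), max_n = 6L) {
  n <- sample(seq_len(max_n), 1L)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    r0 <- sample(1:(shape[1L] - 6L), 1L)
    c0 <- sample(1:(shape[2L] - 6L), 1L)
    h <- sample(3:6, 1L); w <- sample(3:6, 1L)
    masks[[i]] <- block_mask(shape, r0:(r0 + h - 1L), c0:(c0 + w - 1L))
  }
  proposal_set(masks, scores = stats::runif(n), image_shape = shape)
}

# NMS validity predicate: the independent check that a keep/remove partition
# obeys the suppression rule.
nms_valid <- function(original, kept_idx, iou_thr) {
  n <- length(original)
  removed_idx <- setdiff(seq_len(n), kept_idx)
  for (i in kept_idx) for (j in kept_idx) {
    if (i < j &&
        mask_iou(original$masks[[i]], original$masks[[j]]) > iou_thr)
      return(FALSE)
  }
  for (i in removed_idx) {
    suppressor <- FALSE
    for (j in kept_idx) {
      if (mask_iou(original$masks[[i]], original$masks[[j]]) > iou_thr &&
          original$scores[j] > original$scores[i]) {
        suppressor <- TRUE
        break
      }
    }
    if (!suppressor) return(FALSE)
  }
  TRUE
}

# Exhaustive K=3 multi-Otsu over a coarse histogram: maximize between-class
# variance by direct search over threshold pairs.
brute_multiotsu3 <- function(x, nbins = 64L) {
  lo <- min(x); hi <- max(x)
  bin <- pmin(floor((x - lo) / (hi - lo) * nbins) + 1L, nbins)
  best <- NULL
  for (t1 in 1:(nbins - 2L)) for (t2 in (t1 + 1L):(nbins - 1L)) {
    cls <- findInterval(bin, c(t1, t2) + 0.5) + 1L
    if (length(unique(cls)) < 3L) next
    mu <- tapply(x, cls, mean)
    w <- tabulate(cls, 3L) / length(x)
    score <- sum(w * mu^2)
    if (is.null(best) || score > best$score)
      best <- list(score = score, means = as.numeric(mu))
  }
  best
}
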