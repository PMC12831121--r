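test_that("area filtering is strict at both bounds", {
  shape <- c(64L, 64L)  # max area rule: (64/4)^2 = 256
  m9 <- block_mask(shape, 1:3, 1:3)            # 9 px
  m10 <- block_mask(shape, 10:14, 10:11)       # 10 px
  m256 <- block_mask(shape, 1:16, 1:16)        # exactly 256 px
  m_full <- block_mask(shape, 1:64, 1:64)      # 4096 px
  ps <- proposal_set(list(m9, m10, m256, m_full), scores = rep(0.5, 4),
                     image_shape = shape)
  res <- filter_area(ps, filter_config())
  expect_equal(res$keep, c(2L, 3L))            # 10 px and 256 px retained
  expect_equal(res$report$index, c(1L, 4L))
  expect_equal(res$report$stage, c("area_small", "area_large"))
  expect_equal(res$report$diagnostic, c(9, 4096))
})

test_that("the shorter image side sets the maximum-area rule", {
  shape <- c(40L, 200L)  # shorter side 40 -> max area 100
  m <- block_mask(shape, 5:15, 5:15)  # 121 px > 100
  ps <- proposal_set(list(m), scores = 0.5, image_shape = shape)
  res <- filter_area(ps, filter_config())
  expect_equal(res$report$stage, "area_large")
  # an explicit max_area overrides the rule
  res2 <- filter_area(ps, filter_config(max_area = 150))
  expect_equal(res2$keep, 1L)
})

test_that("multi-Otsu recovers exact class structure and matches brute force", {
  # two-valued image, K = 2: class means are the two values
  v <- matrix(0.1, 20, 20); v[5:10, 5:10] <- 0.8
  mo <- multi_otsu(v, K = 2)
  expect_equal(mo$class_means, c(0.1, 0.8))

  # K = 3 on a three-level image
  v3 <- matrix(0.05, 24, 24); v3[1:8, ] <- 0.5; v3[9:12, ] <- 0.95
  mo3 <- multi_otsu(v3, K = 3)
  expect_equal(mo3$class_means, c(0.05, 0.5, 0.95))

  # DP solution matches exhaustive search on noisy trimodal data
  set.seed(8)
  x <- c(rnorm(300, 0.2, 0.03), rnorm(300, 0.5, 0.03), rnorm(200, 0.85, 0.03))
  x <- pmin(pmax(x, 0), 1)
  mine <- multi_otsu(x, K = 3, nbins = 64)
  ref <- brute_multiotsu3(x, nbins = 64)
  expect_equal(sort(mine$class_means), sort(ref$means), tolerance = 1e-12)

  expect_error(multi_otsu(matrix(c(0, 1), 2, 2), K = 3),
               class = "microseg_error")
})

test_that("intensity filtering keeps masks inside the [r1*mu1, r2*muK] band", {
  v <- matrix(0.1, 32, 32)
  v[5:10, 5:10] <- 0.8        # bright cells
  v[20:23, 20:23] <- 0.05     # a dark pocket
  img <- intensity_image(v, normalized = TRUE)
  dark <- block_mask(c(32L, 32L), 20:23, 20:23)   # mean 0.05
  bright <- block_mask(c(32L, 32L), 5:10, 5:10)   # mean 0.8
  ps <- proposal_set(list(dark, bright), scores = c(0.5, 0.9),
                     image_shape = c(32L, 32L))
  res <- filter_intensity(ps, img, filter_config(K = 2))
  # K=2 classes: dark (0.05/0.1 pixels) and bright (0.8); mu1 < 0.13 band floor
  mu <- res$class_means
  expect_lt(0.05, 1.3 * mu[1])          # dark mask falls below the floor
  expect_lte(0.8, 1.3 * mu[2])          # bright mask inside the band
  expect_equal(res$keep, 2L)
  expect_equal(res$report$stage, "intensity_low")
  expect_equal(res$report$diagnostic, 0.05)
})

test_that("mask_iou counts intersection over union", {
  shape <- c(8L, 8L)
  a <- block_mask(shape, 2:3, 2:3)
  expect_equal(mask_iou(a, a), 1)
  b <- block_mask(shape, 6:7, 6:7)
  expect_equal(mask_iou(a, b), 0)
  # 2x2 block vs the same block shifted one column: overlap 2, union 6
  c1 <- block_mask(shape, 2:3, 2:3)
  c2 <- block_mask(shape, 2:3, 3:4)
  expect_equal(mask_iou(c1, c2), 1 / 3)
  expect_equal(mask_iou(c2, c1), 1 / 3)
  expect_error(mask_iou(a & !a, a & !a), class = "microseg_error")
})

test_that("NMS keeps the higher-score mask of each conflicting pair", {
  shape <- c(16L, 16L)
  m <- block_mask(shape, 3:6, 3:6)
  ps <- proposal_set(list(m, m), scores = c(0.9, 0.8), image_shape = shape)
  res <- suppress_overlaps(ps, filter_config())
  expect_equal(res$keep, 1L)
  expect_equal(res$report$stage, "nms")
  expect_equal(res$report$diagnostic, 1)

  # disjoint masks both survive
  ps2 <- proposal_set(list(block_mask(shape, 1:3, 1:3),
                           block_mask(shape, 10:12, 10:12)),
                      scores = c(0.9, 0.8), image_shape = shape)
  expect_equal(suppress_overlaps(ps2, filter_config())$keep, c(1L, 2L))
})

test_that("NMS on an overlap chain keeps the ends: a suppressed mask cannot veto", {
  # A-B and B-C overlap at IoU 0.5 each, A-C are disjoint; scores 0.9/0.8/0.7.
  # B falls to A; C must survive because only *kept* masks suppress.
  shape <- c(8L, 28L)
  x <- block_mask(shape, 1:4, 1:9)
  y <- block_mask(shape, 1:4, 4:12)
  z <- block_mask(shape, 1:4, 7:15)
  expect_equal(mask_iou(x, y), 0.5)
  expect_equal(mask_iou(y, z), 0.5)
  expect_equal(mask_iou(x, z), 3 / 15)  # 0.2, below the 0.3 threshold
  ps <- proposal_set(list(x, y, z), scores = c(0.9, 0.8, 0.7),
                     image_shape = shape)
  cfg <- filter_config()
  res <- suppress_overlaps(ps, cfg)
  expect_equal(res$keep, c(1L, 3L))
  expect_true(nms_valid(ps, res$keep, cfg$iou_threshold))
})

test_that("greedy NMS output satisfies the suppression predicate on random sets", {
  set.seed(77)
  cfg <- filter_config()
  for (rep in 1:100) {
    ps <- random_block_proposals()
    res <- suppress_overlaps(ps, cfg)
    expect_true(nms_valid(ps, res$keep, cfg$iou_threshold))
    # count conservation
    expect_equal(length(res$keep) + nrow(res$report), length(ps))
  }
})

test_that("edge-touching masks are removed at the configured margin", {
  shape <- c(32L, 32L)
  at_col0 <- block_mask(shape, 10:12, 1:3)        # touches column 0
  at_rowH2 <- block_mask(shape, 31, 10:12)        # 0-based row 30 = H-2
  interior <- block_mask(shape, 10:14, 10:14)     # inside [2, 29]
  ps <- proposal_set(list(at_col0, at_rowH2, interior),
                     scores = c(0.5, 0.5, 0.5), image_shape = shape)
  res <- remove_edge_masks(ps, filter_config())
  expect_equal(res$keep, 3L)
  expect_equal(res$report$stage, c("edge", "edge"))

  # margin 0 disables the stage
  res0 <- remove_edge_masks(ps, filter_config(edge_margin = 0))
  expect_equal(res0$keep, 1:3)
  # boundary of the retained band: rows/cols 2..29 (0-based) survive margin 2
  border_ok <- block_mask(shape, 3:5, 3:5)  # 0-based rows 2:4
  ps2 <- proposal_set(list(border_ok), scores = 0.5, image_shape = shape)
  expect_equal(remove_edge_masks(ps2, filter_config())$keep, 1L)
})

test_that("per-mask closing matches brute-force dilation-then-erosion", {
  kern <- microseg:::closing_kernel(1L)
  # ring with a one-pixel gap gets healed
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE
  ring[4:6, 4:6] <- FALSE
  ring[5, 5] <- TRUE  # lone centre => 1-px moat between centre and ring
  set.seed(13)
  masks <- list(ring,
                block_mask(c(9L, 9L), 3:6, 3:6),
                matrix(runif(81) < 0.45, 9, 9) | block_mask(c(9L, 9L), 5, 5))
  ps <- proposal_set(masks, scores = rep(0.5, 3), image_shape = c(9L, 9L))
  closed <- close_masks(ps, filter_config())
  for (i in seq_along(masks)) {
    expect_equal(closed$masks[[i]], brute_close(masks[[i]], kern))
    # closing is extensive: output contains the input
    expect_true(all(closed$masks[[i]][masks[[i]]]))
  }
  # solid convex block unchanged; closing idempotent
  expect_equal(closed$masks[[2]], masks[[2]])
  twice <- close_masks(closed, filter_config())
  expect_equal(twice$masks, closed$masks)
})

test_that("the full chain retains exactly the valid cell of the fixture", {
  fx <- make_refinement_fixture()
  res <- run_postprocess(fx$proposals, fx$image, filter_config())
  expect_equal(res$keep, fx$idx$valid)
  expect_equal(length(res$proposals), 1L)
  # report partitions the input: every index exactly once across kept+removed
  expect_setequal(c(res$keep, res$report$index), seq_len(length(fx$proposals)))
  expect_equal(nrow(res$report), 5L)
  stage_of <- setNames(res$report$stage, res$report$index)
  expect_equal(stage_of[[as.character(fx$idx$speck)]], "area_small")
  expect_equal(stage_of[[as.character(fx$idx$full)]], "area_large")
  expect_equal(stage_of[[as.character(fx$idx$dup_b)]], "nms")
  expect_equal(stage_of[[as.character(fx$idx$dup_a)]], "edge")
  expect_equal(stage_of[[as.character(fx$idx$edge)]], "edge")
})

test_that("stages toggle independently and the pipeline is deterministic", {
  fx <- make_refinement_fixture()
  # without NMS both duplicates survive to the edge stage, which then
  # removes each of them on its own merits
  res <- run_postprocess(fx$proposals, fx$image, filter_config(),
                         stages = c("area", "intensity", "edge", "closing"))
  expect_equal(res$keep, fx$idx$valid)
  dup_rows <- res$report[res$report$index %in%
                           c(fx$idx$dup_a, fx$idx$dup_b), ]
  expect_equal(dup_rows$stage, c("edge", "edge"))

  # empty input: empty output, empty report
  empty <- proposal_set(list(), numeric(0), image_shape = c(64L, 64L))
  res0 <- run_postprocess(empty, fx$image, filter_config())
  expect_equal(length(res0$proposals), 0L)
  expect_equal(nrow(res0$report), 0L)

  # determinism: identical inputs give identical outputs
  a <- run_postprocess(fx$proposals, fx$image, filter_config())
  b <- run_postprocess(fx$proposals, fx$image, filter_config())
  expect_identical(a$keep, b$keep)
  expect_identical(a$proposals$masks, b$proposals$masks)
  expect_identical(a$report, b$report)

  # intensity stage without an image is a configuration error
  expect_error(run_postprocess(fx$proposals, NULL, filter_config()),
               class = "microseg_error")
  expect_error(run_postprocess(fx$proposals, fx$image, filter_config(),
                               stages = "polish"),
               class = "microseg_error")
})

test_that("retained masks obey all bounds before closing", {
  fx <- make_refinement_fixture()
  cfg <- filter_config()
  res <- run_postprocess(fx$proposals, fx$image, cfg,
                         stages = c("area", "intensity", "nms", "edge"))
  amax <- (min(fx$proposals$image_shape) / 4)^2
  for (m in res$proposals$masks) {
    a <- sum(m)
    expect_gte(a, cfg$min_area)
    expect_lte(a, amax)
    idx <- which(m, arr.ind = TRUE)
    expect_true(all(idx[, 1] > cfg$edge_margin &
                      idx[, 1] <= nrow(m) - cfg$edge_margin &
                      idx[, 2] > cfg$edge_margin &
                      idx[, 2] <= ncol(m) - cfg$edge_margin))
  }
  n <- length(res$proposals)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      expect_lte(mask_iou(res$proposals$masks[[i]],
                          res$proposals$masks[[j]]), cfg$iou_threshold)
    }
  }
})
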