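test_that("mean_intensity averages the stacked image under the mask", {
  img <- intensity_image(matrix(7, 6, 6), pixel_scale = 1)
  m <- block_mask(c(6L, 6L), 2:3, 2:4)
  expect_equal(mean_intensity(m, img), 7)

  v <- matrix(0, 4, 4); v[1, 1] <- 2; v[2, 2] <- 4
  m2 <- matrix(FALSE, 4, 4); m2[1, 1] <- TRUE; m2[2, 2] <- TRUE
  expect_equal(mean_intensity(m2, v), 3)

  set.seed(4)
  vr <- matrix(runif(144), 12, 12)
  mr <- matrix(runif(144) < 0.3, 12, 12); mr[5, 5] <- TRUE
  expect_equal(mean_intensity(mr, vr), sum(vr[mr]) / sum(mr))
  expect_error(mean_intensity(matrix(FALSE, 12, 12), vr),
               class = "microseg_error")
})

test_that("fit_rod recovers an axis-aligned rectangle exactly", {
  m <- matrix(FALSE, 60, 60)
  m[11:20, 11:50] <- TRUE  # 10 rows x 40 cols
  fit <- fit_rod(m, pixel_scale = 0.1)
  expect_equal(fit$length_um, 4.0)
  expect_equal(fit$width_um, 1.0)
  expect_equal(fit$box$length_px, 40)
  expect_equal(fit$box$width_px, 10)
})

test_that("fit_rod is translation-invariant and rotation-tolerant", {
  m1 <- matrix(FALSE, 80, 80); m1[11:20, 11:50] <- TRUE
  m2 <- matrix(FALSE, 80, 80); m2[41:50, 21:60] <- TRUE
  f1 <- fit_rod(m1, 0.1); f2 <- fit_rod(m2, 0.1)
  expect_equal(f1$length_um, f2$length_um)
  expect_equal(f1$width_um, f2$width_um)

  # same rectangle rotated 30 degrees, rasterized: within quantization error
  m3 <- rotated_rect_mask(c(80L, 80L), c(40, 40), pi / 6, 40, 10)
  f3 <- fit_rod(m3, 0.1)
  expect_equal(f3$length_um, 4.0, tolerance = 0.1)
  expect_equal(f3$width_um, 1.0, tolerance = 0.1)
  expect_lte(f3$width_um, f3$length_um)

  expect_error(fit_rod(matrix(c(TRUE, rep(FALSE, 35)), 6, 6), 0.1),
               class = "microseg_error")  # below 5 px
})

test_that("rod parameters are recovered on synthetic spherocylinders", {
  set.seed(19)
  scale <- 20 / 256
  rel_L <- rel_W <- numeric(60)
  for (i in 1:60) {
    L <- runif(1, 2, 5); W <- runif(1, 0.6, 1.2)
    ang <- runif(1, 0, pi)
    m <- render_rod(center = runif(2, 45, 210), angle = ang,
                    length_um = L, width_um = W, pixel_scale = scale,
                    image_size = 256L)
    fit <- fit_rod(m, scale)
    rel_L[i] <- abs(fit$length_um - L) / L
    rel_W[i] <- abs(fit$width_um - W) / W
  }
  expect_lte(median(rel_L), 0.10)
  expect_lte(median(rel_W), 0.10)
})

test_that("rod_volume implements the spherocylinder model", {
  expect_equal(rod_volume(3.215, 0.865), 1.720, tolerance = 5e-4)
  # sphere limit: zero cylinder section
  expect_equal(rod_volume(1, 1), 4 / 3 * pi * 0.5^3)
  # hand-evaluated: pi*0.25*1 + (4/3)*pi*0.125
  expect_equal(rod_volume(2, 1), pi * 0.25 + 4 / 3 * pi * 0.125)
  expect_equal(rod_volume(2, 1), 1.3090, tolerance = 1e-4)
  expect_error(rod_volume(1, 2), class = "microseg_error")
  expect_error(rod_volume(1, 0), class = "microseg_error")
})

test_that("rod_volume grows monotonically in length and width", {
  Ls <- seq(1.5, 5, by = 0.25)
  for (W in c(0.6, 0.9, 1.2)) {
    v <- rod_volume(Ls, W)
    expect_true(all(diff(v) > 0))
  }
  Ws <- seq(0.4, 1.4, by = 0.1)
  for (L in c(1.5, 3, 5)) {
    v <- rod_volume(L, Ws)
    expect_true(all(diff(v) > 0))
  }
})

test_that("sphere model: volume, equivalent-area radius, rod consistency", {
  expect_equal(sphere_volume(1.014), 4.367, tolerance = 5e-4)
  expect_equal(sphere_volume(1), 4.18879, tolerance = 1e-5)
  expect_error(sphere_volume(0), class = "microseg_error")

  # rod with L = W = 2r degenerates to the sphere exactly
  for (r in seq(0.1, 5, by = 0.35)) {
    expect_equal(rod_volume(2 * r, 2 * r), sphere_volume(r))
  }

  # rasterized disk of radius 13 px at the native scale
  m <- matrix(FALSE, 64, 64)
  rr <- matrix(rep(1:64 - 0.5, 64), 64)
  cc <- t(rr)
  m[(rr - 32)^2 + (cc - 32)^2 <= 13^2] <- TRUE
  r_est <- fit_sphere(m, 20 / 256)
  expect_equal(r_est, 13 * 20 / 256, tolerance = 0.02)

  # single pixel at unit scale
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(fit_sphere(one, 1), 1 / sqrt(pi))

  # doubling the mask in both axes doubles the radius
  big <- matrix(FALSE, 128, 128)
  big[(matrix(rep(1:128 - 0.5, 128), 128) - 64)^2 +
        (t(matrix(rep(1:128 - 0.5, 128), 128)) - 64)^2 <= 26^2] <- TRUE
  expect_equal(fit_sphere(big, 20 / 256) / r_est, 2, tolerance = 0.02)
  expect_error(fit_sphere(matrix(FALSE, 3, 3), 1), class = "microseg_error")
})

test_that("extract_features builds one consistent row per mask", {
  img <- intensity_image(matrix(5, 100, 100), pixel_scale = 0.1)
  empty <- extract_features(list(), img, "rod")
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("cell_id", "model", "volume_fL", "mean_intensity",
                    "error") %in% names(empty)))

  m1 <- matrix(FALSE, 100, 100); m1[11:20, 11:50] <- TRUE
  m2 <- matrix(FALSE, 100, 100); m2[61:70, 31:70] <- TRUE
  ft <- extract_features(list(m1, m2), img, "rod")
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$cell_id, 1:2)
  expect_equal(ft$volume_fL, rod_volume(ft$L_um, ft$W_um))
  expect_equal(ft$mean_intensity, c(5, 5))
  expect_true(all(is.na(ft$error)))

  # a degenerate mask produces a row-level error, not an abort
  tiny <- matrix(FALSE, 100, 100); tiny[4, 4] <- TRUE
  ft2 <- extract_features(list(m1, tiny), img, "rod")
  expect_equal(nrow(ft2), 2L)
  expect_true(is.na(ft2$error[1]))
  expect_false(is.na(ft2$error[2]))

  # sphere model path
  fts <- extract_features(list(m1), img, "sphere")
  expect_equal(fts$volume_fL, sphere_volume(fts$r_um))

  # unknown pixel scale: geometry in pixels, volumes omitted
  ftp <- extract_features(list(m1), img, "rod", pixel_scale = NA)
  expect_equal(ftp$L_um, 40)
  expect_true(is.na(ftp$volume_fL))
})
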