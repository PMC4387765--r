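test_that("background is the in-mask median", {
  mask <- rect_mask(40, 50, 6, 35, 6, 45)
  m <- matrix(0, 40, 50)
  m[mask$mask] <- 100
  expect_equal(estimate_background(m, mask), 100)

  # 60% at 100, 40% at 200 -> median 100
  n <- sum(mask$mask)
  vals <- c(rep(100, ceiling(0.6 * n)), rep(200, floor(0.4 * n)))
  m[mask$mask] <- vals
  expect_equal(estimate_background(m, mask), 100)

  # one saturated pixel does not move the estimate
  m2 <- m
  m2[which(mask$mask)[1]] <- 65535
  expect_equal(estimate_background(m2, mask), 100)

  empty <- make_mask(matrix(FALSE, 40, 50))
  expect_error(estimate_background(m, empty), class = "fiberflux_empty_mask")
})

test_that("flattening removes the striation template and keeps constants", {
  cfg <- noisefree_config()
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 0)
  sim <- simulate_fiber(pr, cfg, seed = 9)
  mask <- segment_fiber(sim$image)
  flat <- flatten_striation(sim$image, mask)
  # judge template removal on the fiber interior; the segmented mask
  # carries a one-pixel fringe of off-fiber background at the boundary
  resid <- flat[mask$mask & sim$truth$mask]
  expect_lt(max(resid) - min(resid), 0.05 * cfg$ridge_amplitude)

  # a flat image is unchanged
  m <- matrix(300, nrow(flat), ncol(flat))
  flat2 <- flatten_striation(m, mask)
  expect_equal(flat2, m)
})

test_that("flattening preserves punctum amplitude", {
  cfg <- noisefree_config(axis_angle_range_deg = c(0, 0))
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 0)
  tr <- sample_fiber_truth(pr, cfg, seed = 2)
  tr <- place_puncta(tr, data.frame(u_um = 1.1, v_um = 2.3,
                                    radius_um = 0.6, off_zline = TRUE))
  img <- render_fiber_image(tr)
  mask <- segment_fiber(img)
  flat <- flatten_striation(img, mask)
  px <- cfg$pixel_size_um
  r <- floor(tr$puncta$y_um / px) + 1L
  c <- floor(tr$puncta$x_um / px) + 1L
  recovered <- flat[r, c] - median(flat[mask$mask])
  expect_lt(abs(recovered - cfg$puncta_amplitude) / cfg$puncta_amplitude,
            0.15)
})

test_that("the threshold is strictly 10% above the background", {
  mask <- rect_mask(60, 60, 1, 60, 1, 60, 0.2)
  m <- matrix(100, 60, 60)
  m[10:12, 10:12] <- 110        # exactly 1.1 x background: excluded
  ps <- segment_autophagosomes(m, mask, flatten = FALSE)
  expect_equal(ps$background_level, 100)
  expect_equal(ps$threshold_level, 110)
  expect_equal(nrow(ps$records), 0L)

  m[30:32, 30:32] <- 110.0001   # just above: included
  ps2 <- segment_autophagosomes(m, mask, flatten = FALSE)
  expect_equal(nrow(ps2$records), 1L)
  expect_equal(ps2$records$area_px, 9L)

  # a uniform image yields an empty set
  u <- segment_autophagosomes(matrix(100, 60, 60), mask, flatten = FALSE)
  expect_equal(nrow(u$records), 0L)
})

test_that("a rendered disk at twice background is recovered with its area", {
  px <- 0.2
  mask <- rect_mask(60, 60, 1, 60, 1, 60, px)
  m <- matrix(100, 60, 60)
  grid <- fiberflux:::pixel_grid_um(c(60, 60), px)
  disk <- (grid$x - 6.05)^2 + (grid$y - 5.95)^2 <= 1.0^2
  m[disk] <- 200
  ps <- segment_autophagosomes(m, mask, flatten = FALSE)
  expect_equal(nrow(ps$records), 1L)
  expect_lt(abs(ps$records$area_px - 79) / 79, 0.1)
  expect_equal(ps$records$area_um2, ps$records$area_px * px^2)
})

test_that("small components are discarded and connectivity is 8-fold", {
  mask <- rect_mask(30, 30, 1, 30, 1, 30, 0.2)
  m <- matrix(100, 30, 30)
  m[5, 5] <- 1000                      # 1 px: below min_area
  m[cbind(10:13, 10:13)] <- 1000       # 4 px diagonal chain: one component
  ps <- segment_autophagosomes(m, mask, flatten = FALSE)
  expect_equal(nrow(ps$records), 1L)
  expect_equal(ps$records$area_px, 4L)
})

test_that("off-Z-line annotation follows the distance band", {
  px <- 0.2
  mask <- rect_mask(40, 100, 1, 40, 1, 100, px)
  m <- matrix(100, 40, 100)
  m[18:22, 25:26] <- 500   # centroid x = 5.0 um, on the Z-line below
  m[18:22, 50:51] <- 500   # centroid x = 10.0 um, 1 um off
  pairs <- data.frame(left = c(4.6, 8.6), right = c(5.4, 9.4))
  # pair positions are given in absolute x, so the profile origin is -cx
  attr(pairs, "origin_u_um") <- -mask$centroid_um[1]
  attr(pairs, "centroid_um") <- mask$centroid_um
  attr(pairs, "axis_angle_deg") <- 0
  zmap <- infer_zlines(pairs)
  ps <- segment_autophagosomes(m, mask, zmap = zmap, flatten = FALSE)
  rec <- ps$records[order(ps$records$centroid_x_um), ]
  expect_equal(rec$off_zline, c(FALSE, TRUE))
  expect_equal(rec$dist_to_zline_um, c(0, 1), tolerance = 1e-6)

  # without a Z-line map distances are NA and the flag defaults to TRUE
  ps2 <- segment_autophagosomes(m, mask, zmap = NULL, flatten = FALSE)
  expect_true(all(is.na(ps2$records$dist_to_zline_um)))
  expect_true(all(ps2$records$off_zline))
  expect_true(ps2$zline_map_missing)
})

test_that("area ratio is the selected puncta area over the mask area", {
  mask <- rect_mask(50, 100, 1, 50, 1, 100, 0.2)  # 5000 px
  m <- matrix(100, 50, 100)
  m[11:15, 11:20] <- 500   # 50 px
  ps <- segment_autophagosomes(m, mask, flatten = FALSE)
  expect_equal(area_ratio(ps, mask), 0.01)

  empty <- segment_autophagosomes(matrix(100, 50, 100), mask, flatten = FALSE)
  expect_equal(area_ratio(empty, mask), 0)

  zero <- make_mask(matrix(FALSE, 50, 100))
  expect_error(area_ratio(ps, zero), class = "fiberflux_empty_mask")
})

test_that("segmentation is equivariant under intensity scaling", {
  cfg <- sim_config()
  pr <- build_preset("G93A", "3-4mo", "basal")
  sim <- simulate_fiber(pr, cfg, seed = 17)
  mask <- segment_fiber(sim$image)
  lc3 <- sim$image$channels$lc3
  a <- segment_autophagosomes(lc3, mask, flatten = TRUE)
  b <- segment_autophagosomes(lc3 * 3.7, mask, flatten = TRUE)
  expect_identical(a$labels, b$labels)
  expect_equal(b$background_level, 3.7 * a$background_level)
  expect_equal(b$threshold_level, 3.7 * a$threshold_level)
})
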