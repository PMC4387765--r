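test_that("a constant image has no fiber", {
  img <- fiber_image(list(mito = matrix(100, 60, 60)), 0.2)
  expect_error(segment_fiber(img), class = "fiberflux_no_fiber")
})

test_that("segmentation recovers the mask area and orientation", {
  cfg <- noisefree_config()
  pr <- build_preset("WT", "2-3mo", "basal")
  for (s in 1:3) {
    sim <- simulate_fiber(pr, cfg, seed = s)
    mask <- segment_fiber(sim$image)
    expect_lt(abs(mask$area_px - sim$truth$mask_area_px) /
                sim$truth$mask_area_px, 0.05)
    expect_lt(abs(mask$axis_angle - sim$truth$axis_angle), 2)
    expect_equal(mask$area_um2, mask$area_px * cfg$pixel_size_um^2)
  }
})

test_that("axis profile of a constant field is constant, with the right bins", {
  mask <- rect_mask(60, 80, 21, 40, 16, 65)
  m <- matrix(100, 60, 80)
  prof <- axis_profile(m, mask, bin_width_um = 0.2)
  expect_true(all(prof$intensity == 100))
  # 50 columns of pixel centers -> 50 axial bins at one bin per pixel
  expect_equal(nrow(prof), 50L)
  expect_equal(diff(prof$position_um), rep(0.2, 49))
  expect_equal(prof$position_um[1], 0)
})

test_that("axis profile recovers a rendered sinusoid's period", {
  px <- 0.2
  mask <- rect_mask(60, 200, 11, 50, 11, 190, px)
  grid <- fiberflux:::pixel_grid_um(c(60, 200), px)
  m <- 500 + 100 * sin(2 * pi * grid$x / 2.0)
  prof <- axis_profile(m, mask, bin_width_um = px)
  # independent periodogram oracle
  y <- prof$intensity - mean(prof$intensity)
  n <- length(y)
  sp <- Mod(stats::fft(y))[2:floor(n / 2)]
  period <- (n * px) / which.max(sp)
  expect_lt(abs(period - 2.0), 0.1)
})

test_that("mito peak pairing handles the minimal and degenerate cases", {
  pos <- seq(0, 3, by = 0.05)
  bump <- function(c0) exp(-(pos - c0)^2 / (2 * 0.1^2))
  # maxima 0.4 um apart are consistent with a 1 um sarcomere period
  # (the 0.25 * period separation rule would merge them at period 2)
  prof <- fake_profile(pos, 100 + 500 * (bump(1.0) + bump(1.4)))
  pairs <- detect_mito_pairs(prof, config = 1.0)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$left, 1.0, tolerance = 0.02)
  expect_equal(pairs$right, 1.4, tolerance = 0.02)

  flat <- fake_profile(pos, rep(100, length(pos)))
  expect_equal(nrow(detect_mito_pairs(flat, config = 1.0)), 0L)

  lone <- fake_profile(pos, 100 + 500 * bump(1.5))
  lonep <- detect_mito_pairs(lone, config = 1.0)
  expect_equal(nrow(lonep), 0L)
  expect_equal(attr(lonep, "n_unpaired"), 1L)
})

test_that("Z-lines are pair midpoints with a median period", {
  pairs <- data.frame(left = c(1.0, 3.1, 5.0), right = c(1.4, 3.5, 5.4))
  attr(pairs, "origin_u_um") <- 0
  zmap <- infer_zlines(pairs)
  expect_equal(zmap$zline_positions_um, (pairs$left + pairs$right) / 2)
  expect_equal(zmap$period_um, median(diff(zmap$zline_positions_um)))

  one <- infer_zlines(data.frame(left = 1.0, right = 1.4))
  expect_equal(one$zline_positions_um, 1.2)
  expect_true(is.na(one$period_um))

  # pairs symmetric about c give Z-lines symmetric about c
  c0 <- 5
  sym <- data.frame(left = c(2, 7.2), right = c(2.8, 8))
  z <- infer_zlines(sym)$zline_positions_um
  expect_equal(z - c0, -rev(z - c0))

  expect_error(infer_zlines(data.frame(left = numeric(0),
                                       right = numeric(0))),
               class = "fiberflux_empty_zlines")
})

test_that("LC3 alignment offset is the mean distance to the nearest peak", {
  pos <- seq(0, 10, by = 0.05)
  bump <- function(c0) exp(-(pos - c0)^2 / (2 * 0.15^2))
  zpos <- c(2, 4, 6, 8)
  pairs <- data.frame(left = zpos - 0.4, right = zpos + 0.4)
  attr(pairs, "origin_u_um") <- 0
  zmap <- infer_zlines(pairs)

  aligned <- fake_profile(pos, 100 + 500 * Reduce(`+`, lapply(zpos, bump)))
  expect_lt(lc3_alignment_offset(aligned, zmap), 0.02)

  shifted <- fake_profile(pos, 100 + 500 * Reduce(`+`, lapply(zpos + 0.2, bump)))
  expect_equal(lc3_alignment_offset(shifted, zmap), 0.2, tolerance = 0.02)

  flat <- fake_profile(pos, rep(100, length(pos)))
  expect_error(lc3_alignment_offset(flat, zmap),
               class = "fiberflux_no_peaks")
})

test_that("Z-line recovery is rotation invariant", {
  pr <- build_preset("WT", "6wk", "basal")
  offs <- lapply(c(3, 13), function(ang) {
    cfg <- noisefree_config(axis_angle_range_deg = c(ang, ang))
    sim <- simulate_fiber(pr, cfg, seed = 6)
    mask <- segment_fiber(sim$image)
    zmap <- infer_zlines(detect_mito_pairs(
      axis_profile(sim$image, mask, channel = "mito")))
    zline_offsets(sim, mask, zmap)
  })
  expect_equal(length(offs[[1]]), length(offs[[2]]))
  expect_lt(sqrt(mean((offs[[1]] - offs[[2]])^2)), 0.1)
  for (o in offs) expect_lt(sqrt(mean(o^2)), 0.1)
})

test_that("the sarcomere period is recovered on noise-free renders", {
  cfg <- noisefree_config()
  pr <- build_preset("WT", "3-4mo", "basal")
  for (s in 4:5) {
    sim <- simulate_fiber(pr, cfg, seed = s)
    mask <- segment_fiber(sim$image)
    zmap <- infer_zlines(detect_mito_pairs(
      axis_profile(sim$image, mask, channel = "mito")))
    expect_lt(abs(zmap$period_um - cfg$sarcomere_period_um) /
                cfg$sarcomere_period_um, 0.05)
  }
})
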