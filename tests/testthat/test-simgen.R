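test_that("preset table encodes the condition contrasts", {
  ages <- c("6wk", "2-3mo", "3-4mo")
  for (ag in ages) {
    wt_b <- build_preset("WT", ag, "basal")
    wt_i <- build_preset("WT", ag, "induced")
    mu_b <- build_preset("G93A", ag, "basal")
    mu_i <- build_preset("G93A", ag, "induced")
    # mutant basal elevation in puncta and lysosomes, every age
    expect_gt(mu_b$puncta_count_mean, wt_b$puncta_count_mean)
    expect_gt(mu_b$lyso_count_mean, wt_b$lyso_count_mean)
    # induction raises both in wild type
    expect_gt(wt_i$puncta_count_mean, wt_b$puncta_count_mean)
    expect_gt(wt_i$lyso_count_mean, wt_b$lyso_count_mean)
    # induction does not raise puncta in the mutant; drops them past 2 mo
    if (ag == "6wk") {
      expect_lte(mu_i$puncta_count_mean, mu_b$puncta_count_mean)
    } else {
      expect_lt(mu_i$puncta_count_mean, mu_b$puncta_count_mean)
    }
    # mutant lysosomes do not respond to induction
    expect_equal(mu_i$lyso_count_mean, mu_b$lyso_count_mean)
  }
  expect_identical(build_preset("WT", "6wk", "basal"),
                   build_preset("WT", "6wk", "basal"))
})

test_that("unknown condition labels are rejected by name", {
  expect_error(build_preset("HET", "6wk", "basal"), "HET",
               class = "fiberflux_bad_label")
  expect_error(build_preset("WT", "5mo", "basal"), "5mo",
               class = "fiberflux_bad_label")
  expect_error(build_preset("WT", "6wk", "fasted"), "fasted",
               class = "fiberflux_bad_label")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(pixel_size_um = 0), "pixel_size_um")
  expect_error(sim_config(sarcomere_period_um = 0.7, mito_offset_um = 0.4),
               "mito_offset")
  expect_error(sim_config(image_shape = c(-2, 100)), "image_shape")
  expect_error(sim_config(background_level = -1), "amplitude")
})

test_that("truth sampling is seeded and geometrically consistent", {
  cfg <- sim_config()
  pr <- build_preset("G93A", "2-3mo", "basal")
  t1 <- sample_fiber_truth(pr, cfg, seed = 7)
  t2 <- sample_fiber_truth(pr, cfg, seed = 7)
  expect_equal(t1, t2)
  t3 <- sample_fiber_truth(pr, cfg, seed = 8)
  expect_false(isTRUE(all.equal(t1$zline_positions_um, t3$zline_positions_um)))

  # Z-line spacing equals the sarcomere period; count matches fiber length
  expect_equal(diff(t1$zline_positions_um),
               rep(cfg$sarcomere_period_um,
                   length(t1$zline_positions_um) - 1))
  n_expected <- floor(cfg$fiber_length_um / cfg$sarcomere_period_um)
  expect_lte(abs(length(t1$zline_positions_um) - n_expected), 1)

  # all object centers lie inside the mask raster
  px <- cfg$pixel_size_um
  for (df in list(t1$puncta, t1$lysosomes)) {
    r <- floor(df$y_um / px) + 1L
    c <- floor(df$x_um / px) + 1L
    expect_true(all(t1$mask[cbind(r, c)]))
  }
  # truth bookkeeping is self-consistent
  expect_equal(t1$mask_area_px, sum(t1$mask))
  expect_equal(t1$area_ratio_truth, t1$puncta_area_px / t1$mask_area_px)
})

test_that("degenerate rates give empty object lists", {
  cfg <- sim_config()
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 0)
  tr <- sample_fiber_truth(pr, cfg, seed = 1)
  expect_equal(nrow(tr$puncta), 0L)
  expect_equal(nrow(tr$lysosomes), 0L)
  expect_equal(tr$area_ratio_truth, 0)
})

test_that("object counts are Poisson with the preset mean", {
  cfg <- sim_config()
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 30,
                         contact_prob = 0)
  counts <- vapply(1:500, function(s)
    nrow(sample_fiber_truth(pr, cfg, seed = s)$lysosomes), numeric(1))
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30 / 500))
})

test_that("noise-free rendering matches the analytic template", {
  cfg <- noisefree_config()
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 0)
  tr <- sample_fiber_truth(pr, cfg, seed = 3)
  img <- render_fiber_image(tr)
  expect_identical(img$channels$lc3, render_fiber_image(tr)$channels$lc3)

  lc3 <- img$channels$lc3
  expect_true(all(lc3[!tr$mask] == cfg$dark_level))
  # far from any Z-line the LC3 channel is exactly the background
  grid <- fiberflux:::pixel_grid_um(dim(lc3), cfg$pixel_size_um)
  fc <- fiber_frame_coords(grid$x, grid$y, tr$center_um, tr$axis_angle)
  far <- tr$mask & matrix(
    fiberflux:::dist_to_nearest_sorted(fc$u, tr$zline_positions_um) > 1.05,
    nrow(lc3), ncol(lc3))
  expect_lt(max(abs(lc3[far] - cfg$background_level)), 1)
  # ridge crest reaches background + ridge amplitude
  expect_gt(max(lc3[tr$mask]),
            cfg$background_level + 0.95 * cfg$ridge_amplitude)
})

test_that("mitochondrial rows peak at z +/- offset in the rendered image", {
  cfg <- noisefree_config(axis_angle_range_deg = c(4, 4))
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 0)
  sim <- simulate_fiber(pr, cfg, seed = 11)
  mask <- segment_fiber(sim$image)
  prof <- axis_profile(sim$image, mask, channel = "mito")
  pk <- find_profile_peaks(prof$position_um, prof$intensity,
                           min_sep = 0.25 * cfg$sarcomere_period_um)
  tr <- sim$truth
  th <- tr$axis_angle * pi / 180
  rows_truth <- sort(c(tr$zline_positions_um - cfg$mito_offset_um,
                       tr$zline_positions_um + cfg$mito_offset_um))
  rx <- tr$center_um[1] + rows_truth * cos(th)
  ry <- tr$center_um[2] + rows_truth * sin(th)
  fc <- fiber_frame_coords(rx, ry, mask$centroid_um, mask$axis_angle)
  pk_u <- attr(prof, "origin_u_um") + pk$position
  offs <- fiberflux:::dist_to_nearest_sorted(sort(fc$u), sort(pk_u))
  expect_lt(max(offs), 0.08)
  expect_equal(nrow(pk), length(rows_truth))
})

test_that("a rendered disk's half-maximum footprint matches the analytic area", {
  # ridge switched off so the only structure is the disk itself
  cfg <- noisefree_config(axis_angle_range_deg = c(0, 0),
                          ridge_amplitude = 0)
  pr <- condition_preset(puncta_count_mean = 0, lyso_count_mean = 0)
  tr <- sample_fiber_truth(pr, cfg, seed = 2)
  tr <- place_puncta(tr, data.frame(u_um = 0.13, v_um = -0.07,
                                    radius_um = 1.0, off_zline = TRUE))
  img <- render_fiber_image(tr)
  half <- cfg$background_level + cfg$puncta_amplitude / 2
  n <- sum(img$channels$lc3 > half)
  expect_lt(abs(n - 79) / 79, 0.1)
})

test_that("integrated LC3 signal grows with total truth puncta area", {
  cfg <- noisefree_config()
  totals <- vapply(c(3, 10, 25, 50), function(mu) {
    pr <- condition_preset(puncta_count_mean = mu, lyso_count_mean = 0)
    sim <- simulate_fiber(pr, cfg, seed = 40 + mu)
    sum(sim$image$channels$lc3[sim$truth$mask]) -
      cfg$background_level * sim$truth$mask_area_px
  }, numeric(1))
  expect_true(all(diff(totals) > 0))
})

test_that("cohorts are reproducible, complete and faithfully written", {
  cfg <- small_config(master_seed = 5L)
  presets <- default_preset_table()[c(1, 2, 7), ]
  out <- withr::local_tempdir()
  man <- generate_cohort(cfg, presets, n_fibers_per_condition = 5,
                         out_dir = out)
  expect_equal(nrow(man), 15L)
  expect_true(all(file.exists(file.path(out, man$file))))
  expect_true(file.exists(file.path(out, "manifest.csv")))

  truths <- attr(man, "truths")
  expect_equal(man$truth_puncta_count,
               vapply(truths, function(t) nrow(t$puncta), numeric(1)))
  expect_equal(man$truth_lyso_count,
               vapply(truths, function(t) nrow(t$lysosomes), numeric(1)))

  man2 <- generate_cohort(cfg, presets, n_fibers_per_condition = 5,
                          out_dir = withr::local_tempdir())
  expect_equal(as.data.frame(man), as.data.frame(man2))

  # TIFF round trip preserves the (integer-rounded) intensities
  sim <- simulate_fiber(build_preset(presets$genotype[1],
                                     presets$age_group[1],
                                     presets$treatment[1]),
                        cfg, seed = man$seed[1])
  back <- read_fiber_tiff(file.path(out, man$file[1]),
                          pixel_size_um = cfg$pixel_size_um)
  expect_equal(back$channels$lc3, round(sim$image$channels$lc3))
  expect_equal(back$channels$lyso, round(sim$image$channels$lyso))

  expect_error(generate_cohort(cfg, presets, 0), "n_fibers")
})
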