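#' Simulation configuration for synthetic fiber images
#'
#' Defines the geometry, intensity scale and noise model of the synthetic
#' striated-fiber generator. The rendered fiber is an elongated band on a
#' dark background: transverse Z-lines with a ~2 um sarcomere period, an
#' LC3 baseline ridge on each Z-line, mitochondria as Gaussian-profile
#' double rows flanking each Z-line at `mito_offset_um`, plus hard-edged
#' disks for autophagosome puncta (LC3 channel) and lysosomes (lyso
#' channel). Intensities are arbitrary units on a 16-bit scale.
#'
#' @param pixel_size_um pixel size (default 0.2 um/px).
#' @param image_shape integer (rows, cols) of the raster.
#' @param sarcomere_period_um Z-line spacing (default 2.0 um).
#' @param mito_offset_um distance from a Z-line to each mitochondrial row
#'   (default 0.4 um).
#' @param ridge_amplitude peak height of the LC3 baseline striation (a.u.).
#' @param background_level in-fiber baseline intensity (a.u.).
#' @param read_noise_sd additive Gaussian read noise sd (a.u.).
#' @param shot_noise logical; Poisson shot noise applied on the photon
#'   scale (`photons_per_au` photons per intensity unit), so the noise sd
#'   in a.u. is sqrt(intensity / photons_per_au).
#' @param photons_per_au detector calibration: photons per arbitrary
#'   intensity unit (default 4).
#' @param master_seed integer master seed for cohort generation.
#' @param fiber_width_um,fiber_length_um fiber band dimensions.
#' @param axis_angle_range_deg range the fiber long-axis orientation is
#'   drawn from (uniform), so orientation must genuinely be estimated.
#' @param dark_level off-fiber background (a.u.).
#' @param ridge_sigma_um,mito_sigma_um Gaussian widths of the LC3 ridge
#'   and mitochondrial rows.
#' @param mito_amplitude,puncta_amplitude,lyso_amplitude peak heights
#'   added above the in-fiber baseline (a.u.).
#' @param lyso_radius_um_range lysosome radius range (uniform).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(pixel_size_um = 0.2,
                       image_shape = c(160L, 360L),
                       sarcomere_period_um = 2.0,
                       mito_offset_um = 0.4,
                       ridge_amplitude = 800,
                       background_level = 500,
                       read_noise_sd = 10,
                       shot_noise = TRUE,
                       photons_per_au = 4,
                       master_seed = 1L,
                       fiber_width_um = 24,
                       fiber_length_um = 60,
                       axis_angle_range_deg = c(-15, 15),
                       dark_level = 50,
                       ridge_sigma_um = 0.25,
                       mito_sigma_um = 0.15,
                       mito_amplitude = 1200,
                       puncta_amplitude = 3 * background_level,
                       lyso_amplitude = 3 * background_level) {
  cfg <- list(pixel_size_um = pixel_size_um,
              image_shape = as.integer(image_shape),
              sarcomere_period_um = sarcomere_period_um,
              mito_offset_um = mito_offset_um,
              ridge_amplitude = ridge_amplitude,
              background_level = background_level,
              read_noise_sd = read_noise_sd,
              shot_noise = isTRUE(shot_noise),
              photons_per_au = photons_per_au,
              master_seed = as.integer(master_seed),
              fiber_width_um = fiber_width_um,
              fiber_length_um = fiber_length_um,
              axis_angle_range_deg = axis_angle_range_deg,
              dark_level = dark_level,
              ridge_sigma_um = ridge_sigma_um,
              mito_sigma_um = mito_sigma_um,
              mito_amplitude = mito_amplitude,
              puncta_amplitude = puncta_amplitude,
              lyso_amplitude = lyso_amplitude)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (!(cfg$pixel_size_um > 0))
    stop("pixel_size_um must be > 0")
  if (!(cfg$sarcomere_period_um > 2 * cfg$mito_offset_um))
    stop("sarcomere_period_um must exceed 2 * mito_offset_um")
  if (any(cfg$image_shape <= 0L) || length(cfg$image_shape) != 2L)
    stop("image_shape must be two positive integers (rows, cols)")
  amps <- c(cfg$ridge_amplitude, cfg$background_level, cfg$read_noise_sd,
            cfg$mito_amplitude, cfg$puncta_amplitude, cfg$lyso_amplitude,
            cfg$dark_level)
  if (any(amps < 0)) stop("amplitudes and noise levels must be >= 0")
  invisible(cfg)
}

.genotypes <- c("WT", "G93A")
.age_groups <- c("6wk", "2-3mo", "3-4mo")
.treatments <- c("basal", "induced")

# Calibrated preset table. Values are calibration choices reproducing the
# qualitative condition contrasts (mutant basal elevation in puncta and
# lysosomes at all ages; induction raises both in wild type; induction
# fails to raise - and past 2 months lowers - puncta in the mutant).
.preset_table <- local({
  tab <- expand.grid(genotype = .genotypes, age_group = .age_groups,
                     treatment = .treatments, stringsAsFactors = FALSE)
  key <- paste(tab$genotype, tab$age_group, tab$treatment, sep = "|")
  puncta <- c("WT|6wk|basal" = 6,    "WT|2-3mo|basal" = 6,    "WT|3-4mo|basal" = 6,
              "WT|6wk|induced" = 25, "WT|2-3mo|induced" = 25, "WT|3-4mo|induced" = 25,
              "G93A|6wk|basal" = 15, "G93A|2-3mo|basal" = 18, "G93A|3-4mo|basal" = 20,
              "G93A|6wk|induced" = 15, "G93A|2-3mo|induced" = 8, "G93A|3-4mo|induced" = 8)
  lyso <- c("WT|6wk|basal" = 60,    "WT|2-3mo|basal" = 60,    "WT|3-4mo|basal" = 60,
            "WT|6wk|induced" = 150, "WT|2-3mo|induced" = 150, "WT|3-4mo|induced" = 150,
            "G93A|6wk|basal" = 130, "G93A|2-3mo|basal" = 135, "G93A|3-4mo|basal" = 140,
            "G93A|6wk|induced" = 130, "G93A|2-3mo|induced" = 135, "G93A|3-4mo|induced" = 140)
  tab$puncta_count_mean <- unname(puncta[key])
  tab$lyso_count_mean <- unname(lyso[key])
  tab$contact_prob <- 0.9
  tab$puncta_radius_um_min <- 0.3
  tab$puncta_radius_um_max <- 0.8
  tab
})

#' Condition preset for the synthetic cohort generator
#'
#' Returns the deterministic preset (expected autophagosome puncta per
#' imaged fiber segment, expected free lysosomes, puncta radius range and
#' LC3-lysosome contact probability) for one experimental condition.
#'
#' @param genotype `"WT"` or `"G93A"`.
#' @param age_group `"6wk"`, `"2-3mo"` or `"3-4mo"`.
#' @param treatment `"basal"` (regular diet) or `"induced"` (starvation
#'   plus colchicine).
#' @return object of class `condition_preset`.
#' @export
build_preset <- function(genotype, age_group, treatment) {
  if (!genotype %in% .genotypes)
    stop_fiberflux("fiberflux_bad_label", "unknown genotype '%s'", genotype)
  if (!age_group %in% .age_groups)
    stop_fiberflux("fiberflux_bad_label", "unknown age_group '%s'", age_group)
  if (!treatment %in% .treatments)
    stop_fiberflux("fiberflux_bad_label", "unknown treatment '%s'", treatment)
  row <- .preset_table[.preset_table$genotype == genotype &
                         .preset_table$age_group == age_group &
                         .preset_table$treatment == treatment, ]
  structure(list(genotype = genotype, age_group = age_group,
                 treatment = treatment,
                 puncta_count_mean = row$puncta_count_mean,
                 puncta_radius_um_range = c(row$puncta_radius_um_min,
                                            row$puncta_radius_um_max),
                 lyso_count_mean = row$lyso_count_mean,
                 contact_prob = row$contact_prob),
            class = "condition_preset")
}

#' The full default preset table
#' @return data.frame with one row per condition.
#' @export
default_preset_table <- function() .preset_table

#' Construct a custom condition preset
#'
#' [build_preset()] returns the calibrated defaults; this constructor
#' builds a preset with arbitrary abundances, e.g. for calibration
#' studies sweeping puncta density or contact probability.
#'
#' @param genotype,age_group,treatment condition labels (free-form here).
#' @param puncta_count_mean expected autophagosome puncta per fiber
#'   segment (>= 0).
#' @param lyso_count_mean expected free (non-punctum-associated)
#'   lysosomes per fiber segment (>= 0).
#' @param contact_prob probability that an LC3 punctum has an adjacent
#'   lysosome, in [0, 1].
#' @param puncta_radius_um_range (min, max) punctum radius in microns.
#' @return object of class `condition_preset`.
#' @export
condition_preset <- function(genotype = "WT", age_group = "2-3mo",
                             treatment = "basal", puncta_count_mean = 6,
                             lyso_count_mean = 60, contact_prob = 0.9,
                             puncta_radius_um_range = c(0.3, 0.8)) {
  stopifnot(puncta_count_mean >= 0, lyso_count_mean >= 0,
            contact_prob >= 0, contact_prob <= 1,
            length(puncta_radius_um_range) == 2,
            puncta_radius_um_range[1] > 0,
            puncta_radius_um_range[1] <= puncta_radius_um_range[2])
  structure(list(genotype = genotype, age_group = age_group,
                 treatment = treatment,
                 puncta_count_mean = puncta_count_mean,
                 puncta_radius_um_range = puncta_radius_um_range,
                 lyso_count_mean = lyso_count_mean,
                 contact_prob = contact_prob),
            class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("condition_preset %s / %s / %s: puncta ~Pois(%g), r in [%g, %g] um, lyso ~Pois(%g), contact_prob %g\n",
              x$genotype, x$age_group, x$treatment, x$puncta_count_mean,
              x$puncta_radius_um_range[1], x$puncta_radius_um_range[2],
              x$lyso_count_mean, x$contact_prob))
  invisible(x)
}

# boundary gap (um) between two disks
.gap <- function(ux, vx, rx, uy, vy, ry)
  sqrt((ux - uy)^2 + (vx - vy)^2) - rx - ry

#' Sample the ground truth of one synthetic fiber
#'
#' Draws a fiber orientation, Z-line positions, autophagosome puncta and
#' lysosomes for one fiber. Puncta and free-lysosome counts are Poisson
#' with the preset means; positions are uniform in the fiber band with a
#' minimum-spacing rejection rule (up to 1000 tries, then overlap is
#' accepted). Each LC3 punctum independently receives one adjacent
#' lysosome (boundary gap 0 to 0.2 um) with probability `contact_prob`;
#' all other lysosomes are kept at a boundary gap of at least 0.7 um from
#' every punctum so truth contacts are unambiguous.
#'
#' @param preset a [build_preset()] result.
#' @param config a [sim_config()].
#' @param seed integer seed; identical seeds give identical truth.
#' @return object of class `fiber_truth` with elements `mask` (logical
#'   raster), `axis_angle` (deg), `center_um`, `zline_positions_um`
#'   (axial, relative to the fiber center), `puncta` and `lysosomes`
#'   (data.frames), truth pixel footprints and the truth area ratio.
#' @export
sample_fiber_truth <- function(preset, config, seed) {
  stopifnot(inherits(preset, "condition_preset"), inherits(config, "sim_config"))
  validate_sim_config(config)
  seed <- as.integer(seed %% .Machine$integer.max)
  withr::local_seed(seed)

  px <- config$pixel_size_um
  shape <- config$image_shape
  L <- config$fiber_length_um
  W <- config$fiber_width_um
  center <- c(shape[2] * px / 2, shape[1] * px / 2)  # (x, y)
  angle <- stats::runif(1, config$axis_angle_range_deg[1],
                        config$axis_angle_range_deg[2])

  # Z-lines: one phase draw, equally spaced, 0.5 um end margin
  period <- config$sarcomere_period_um
  phase <- stats::runif(1, 0, period)
  zmin <- -L / 2 + 0.5
  zmax <- L / 2 - 0.5
  k0 <- ceiling((zmin - phase) / period)
  k1 <- floor((zmax - phase) / period)
  zlines <- phase + (k0:k1) * period

  # mask raster
  grid <- pixel_grid_um(shape, px)
  fc <- fiber_frame_coords(grid$x, grid$y, center, angle)
  mask <- abs(fc$u) <= L / 2 & abs(fc$v) <= W / 2
  dim(mask) <- shape

  # a candidate object must lie wholly inside both the fiber band and the
  # raster (the rotated band's corners may be clipped by the field of view),
  # with a 0.5 um sarcolemmal margin: autophagosomes and lysosomes are
  # intracellular and segmentation cannot follow objects cut by the edge
  margin <- 0.5
  th0 <- angle * pi / 180
  in_raster <- function(u, v, r) {
    x <- center[1] + u * cos(th0) - v * sin(th0)
    y <- center[2] + u * sin(th0) + v * cos(th0)
    x >= r + margin & x <= shape[2] * px - r - margin &
      y >= r + margin & y <= shape[1] * px - r - margin
  }

  rr <- preset$puncta_radius_um_range
  n_p <- stats::rpois(1, preset$puncta_count_mean)
  p_off <- 0.9  # fraction of puncta formed off the Z-line
  puncta <- data.frame(u_um = numeric(0), v_um = numeric(0),
                       radius_um = numeric(0), off_zline = logical(0))
  if (n_p > 0) {
    for (i in seq_len(n_p)) {
      r <- stats::runif(1, rr[1], rr[2])
      off <- stats::runif(1) < p_off
      placed <- FALSE
      for (try in seq_len(1000)) {
        u <- stats::runif(1, -L / 2 + r + margin, L / 2 - r - margin)
        v <- stats::runif(1, -W / 2 + r + margin, W / 2 - r - margin)
        dz <- dist_to_nearest_sorted(u, zlines)
        if (off && dz <= 0.25) next        # keep off-Z-line puncta clear of the band
        if (!off) u <- nearest_sorted(u, zlines)
        if (!in_raster(u, v, r)) next
        if (nrow(puncta) > 0) {
          gaps <- .gap(u, v, r, puncta$u_um, puncta$v_um, puncta$radius_um)
          if (min(gaps) < mean(c(r, puncta$radius_um))) next
        }
        placed <- TRUE
        break
      }
      if (!placed) {
        u <- stats::runif(1, -L / 2 + r + margin, L / 2 - r - margin)
        v <- stats::runif(1, -W / 2 + r + margin, W / 2 - r - margin)
      }
      puncta <- rbind(puncta, data.frame(u_um = u, v_um = v, radius_um = r,
                                         off_zline = off))
    }
  }

  lr <- c(0.3, 0.5)  # lysosome radius range (um)
  lyso <- data.frame(u_um = numeric(0), v_um = numeric(0),
                     radius_um = numeric(0), contacting = logical(0),
                     punctum_id = integer(0))
  # contacting lysosomes: one Bernoulli draw per punctum
  if (nrow(puncta) > 0) {
    for (i in seq_len(nrow(puncta))) {
      if (stats::runif(1) >= preset$contact_prob) next
      r <- stats::runif(1, lr[1], lr[2])
      for (try in seq_len(1000)) {
        ang <- stats::runif(1, 0, 2 * pi)
        gap <- stats::runif(1, 0, 0.2)
        d <- puncta$radius_um[i] + r + gap
        u <- puncta$u_um[i] + d * cos(ang)
        v <- puncta$v_um[i] + d * sin(ang)
        if (abs(u) > L / 2 - r - margin || abs(v) > W / 2 - r - margin) next
        if (!in_raster(u, v, r)) next
        others <- setdiff(seq_len(nrow(puncta)), i)
        if (length(others) &&
            min(.gap(u, v, r, puncta$u_um[others], puncta$v_um[others],
                     puncta$radius_um[others])) < 0.7) next
        if (nrow(lyso) > 0 &&
            min(.gap(u, v, r, lyso$u_um, lyso$v_um, lyso$radius_um)) < 0.4) next
        lyso <- rbind(lyso, data.frame(u_um = u, v_um = v, radius_um = r,
                                       contacting = TRUE, punctum_id = i))
        break
      }
    }
  }
  # free lysosomes, kept clear of all puncta
  n_l <- stats::rpois(1, preset$lyso_count_mean)
  for (i in seq_len(n_l)) {
    r <- stats::runif(1, lr[1], lr[2])
    placed <- FALSE
    for (try in seq_len(1000)) {
      u <- stats::runif(1, -L / 2 + r + margin, L / 2 - r - margin)
      v <- stats::runif(1, -W / 2 + r + margin, W / 2 - r - margin)
      if (!in_raster(u, v, r)) next
      if (nrow(puncta) > 0 &&
          min(.gap(u, v, r, puncta$u_um, puncta$v_um, puncta$radius_um)) < 0.7) next
      if (nrow(lyso) > 0 &&
          min(.gap(u, v, r, lyso$u_um, lyso$v_um, lyso$radius_um)) < 0.4) next
      placed <- TRUE
      break
    }
    if (!placed) next  # overfull fiber: drop rather than fabricate contacts
    lyso <- rbind(lyso, data.frame(u_um = u, v_um = v, radius_um = r,
                                   contacting = FALSE, punctum_id = NA_integer_))
  }

  # image-frame centers
  th <- angle * pi / 180
  to_xy <- function(u, v)
    list(x = center[1] + u * cos(th) - v * sin(th),
         y = center[2] + u * sin(th) + v * cos(th))
  if (nrow(puncta)) { xy <- to_xy(puncta$u_um, puncta$v_um); puncta$x_um <- xy$x; puncta$y_um <- xy$y }
  if (nrow(lyso)) { xy <- to_xy(lyso$u_um, lyso$v_um); lyso$x_um <- xy$x; lyso$y_um <- xy$y }

  # pixelized truth footprint of the puncta (centers within radius, in mask)
  ppx <- 0L
  if (nrow(puncta)) {
    inside <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(nrow(puncta))) {
      inside <- inside | ((grid$x - puncta$x_um[i])^2 +
                            (grid$y - puncta$y_um[i])^2 <= puncta$radius_um[i]^2)
    }
    ppx <- sum(inside & mask)
  }
  mask_px <- sum(mask)

  structure(list(mask = mask, axis_angle = angle, center_um = center,
                 zline_positions_um = zlines,
                 puncta = puncta, lysosomes = lyso,
                 puncta_area_px = ppx, mask_area_px = mask_px,
                 area_ratio_truth = ppx / mask_px,
                 config = config, preset = preset, seed = seed),
            class = "fiber_truth")
}

#' @export
print.fiber_truth <- function(x, ...) {
  cat(sprintf("fiber_truth: angle %.1f deg, %d Z-lines, %d puncta, %d lysosomes (%d contacting), truth area ratio %.4f\n",
              x$axis_angle, length(x$zline_positions_um), nrow(x$puncta),
              nrow(x$lysosomes), sum(x$lysosomes$contacting),
              x$area_ratio_truth))
  invisible(x)
}

#' Render a synthetic fiber image from its ground truth
#'
#' Produces the three channels: `lc3` = in-fiber baseline + Gaussian
#' Z-line ridge + hard-edged puncta disks; `mito` = baseline + Gaussian
#' double rows at each Z-line +/- `mito_offset_um`; `lyso` = baseline +
#' lysosome disks. Optional Poisson shot noise and Gaussian read noise are
#' applied per pixel; intensities are clipped at 0. Objects whose disks
#' extend beyond the raster are clipped; the clipped pixel count is
#' reported in the image metadata.
#'
#' @param truth a [sample_fiber_truth()] result.
#' @param config the [sim_config()] used to sample `truth` (geometry must
#'   match); defaults to the config stored in `truth`.
#' @return a [fiber_image()] with the truth attached as metadata.
#' @export
render_fiber_image <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "fiber_truth"), inherits(config, "sim_config"))
  px <- config$pixel_size_um
  shape <- config$image_shape
  grid <- pixel_grid_um(shape, px)
  fc <- fiber_frame_coords(grid$x, grid$y, truth$center_um, truth$axis_angle)
  mask <- truth$mask
  z <- truth$zline_positions_um

  base <- matrix(config$dark_level, shape[1], shape[2])
  base[mask] <- config$background_level

  # LC3: ridge on each Z-line + puncta disks
  lc3 <- base
  if (length(z)) {
    dz <- dist_to_nearest_sorted(fc$u[mask], z)
    lc3[mask] <- lc3[mask] +
      config$ridge_amplitude * exp(-dz^2 / (2 * config$ridge_sigma_um^2))
  }
  clipped <- 0L
  add_disks <- function(img, df, amplitude) {
    for (i in seq_len(nrow(df))) {
      r <- df$radius_um[i]
      r_lo <- max(1L, floor((df$y_um[i] - r) / px))
      r_hi <- min(shape[1], ceiling((df$y_um[i] + r) / px) + 1L)
      c_lo <- max(1L, floor((df$x_um[i] - r) / px))
      c_hi <- min(shape[2], ceiling((df$x_um[i] + r) / px) + 1L)
      if (r_lo > r_hi || c_lo > c_hi) {
        clipped <<- clipped + sum(((grid$x - df$x_um[i])^2 +
                                     (grid$y - df$y_um[i])^2) <= r^2)
        next
      }
      rows <- r_lo:r_hi
      cols <- c_lo:c_hi
      sub_x <- grid$x[rows, cols, drop = FALSE]
      sub_y <- grid$y[rows, cols, drop = FALSE]
      disk <- (sub_x - df$x_um[i])^2 + (sub_y - df$y_um[i])^2 <= r^2
      n_analytic <- sum(((grid$x - df$x_um[i])^2 + (grid$y - df$y_um[i])^2) <= r^2)
      clipped <<- clipped + (n_analytic - sum(disk)) # disks cut by the raster edge
      img[rows, cols][disk] <- img[rows, cols][disk] + amplitude
    }
    img
  }
  if (nrow(truth$puncta))
    lc3 <- add_disks(lc3, truth$puncta, config$puncta_amplitude)

  # mito: double rows at z +/- offset
  mito <- base
  if (length(z)) {
    rows_pos <- sort(c(z - config$mito_offset_um, z + config$mito_offset_um))
    dm <- dist_to_nearest_sorted(fc$u[mask], rows_pos)
    mito[mask] <- mito[mask] +
      config$mito_amplitude * exp(-dm^2 / (2 * config$mito_sigma_um^2))
  }

  lyso <- base
  if (nrow(truth$lysosomes))
    lyso <- add_disks(lyso, truth$lysosomes, config$lyso_amplitude)

  chans <- list(lc3 = lc3, mito = mito, lyso = lyso)
  if (config$shot_noise || config$read_noise_sd > 0) {
    withr::local_seed((truth$seed + 777L) %% .Machine$integer.max)
    chans <- lapply(chans, function(ch) {
      v <- as.vector(ch)
      if (config$shot_noise)
        v <- stats::rpois(length(v), v * config$photons_per_au) /
          config$photons_per_au
      if (config$read_noise_sd > 0)
        v <- v + stats::rnorm(length(v), 0, config$read_noise_sd)
      matrix(pmax(v, 0), shape[1], shape[2])
    })
  }
  fiber_image(chans, px,
              condition = truth$preset[c("genotype", "age_group", "treatment")],
              metadata = list(truth = truth, clipped_px = clipped))
}

#' Simulate one fiber (truth + rendered image) for a condition
#'
#' @inheritParams sample_fiber_truth
#' @return list with elements `truth` and `image`.
#' @export
simulate_fiber <- function(preset, config, seed) {
  truth <- sample_fiber_truth(preset, config, seed)
  list(truth = truth, image = render_fiber_image(truth, config))
}

#' @keywords internal
fiber_seed <- function(master_seed, cond_idx, fiber_idx) {
  as.integer((as.double(master_seed) * 100003 + cond_idx * 10007 +
                fiber_idx * 101) %% 2147483647)
}

#' Generate a cohort of synthetic fibers
#'
#' One multi-page TIFF per fiber (pages lc3, mito, lyso) plus a manifest
#' CSV. Each fiber's seed is derived from `(master_seed, condition index,
#' fiber index)`, so the cohort is reproducible regardless of generation
#' order.
#'
#' @param config a [sim_config()]; its `master_seed` fixes everything.
#' @param presets list of [build_preset()] results (or a data.frame with
#'   genotype/age_group/treatment columns).
#' @param n_fibers_per_condition fibers per condition (> 0).
#' @param out_dir output directory (created if missing); when `NULL` no
#'   files are written and images are returned in memory.
#' @return the manifest data.frame (columns: file, genotype, age_group,
#'   treatment, seed, truth_puncta_count, truth_area_ratio,
#'   truth_lyso_count, truth_contact_prob), with the per-fiber truths (and
#'   images when `out_dir` is `NULL`) attached as attributes.
#' @export
generate_cohort <- function(config, presets, n_fibers_per_condition,
                            out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (n_fibers_per_condition <= 0) stop("n_fibers_per_condition must be > 0")
  if (is.data.frame(presets)) {
    presets <- lapply(seq_len(nrow(presets)), function(i)
      build_preset(presets$genotype[i], presets$age_group[i], presets$treatment[i]))
  }
  if (inherits(presets, "condition_preset")) presets <- list(presets)
  write_files <- !is.null(out_dir)
  if (write_files) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  rows <- list(); truths <- list(); images <- list()
  k <- 0L
  for (ci in seq_along(presets)) {
    pr <- presets[[ci]]
    for (fi in seq_len(n_fibers_per_condition)) {
      k <- k + 1L
      seed <- fiber_seed(config$master_seed, ci, fi)
      sim <- simulate_fiber(pr, config, seed)
      fname <- sprintf("%s_%s_%s_f%03d.tif", pr$genotype, pr$age_group,
                       pr$treatment, fi)
      if (write_files) {
        write_fiber_tiff(sim$image, file.path(out_dir, fname))
      } else {
        images[[k]] <- sim$image
      }
      truths[[k]] <- sim$truth
      tr <- sim$truth
      rows[[k]] <- data.frame(file = fname, genotype = pr$genotype,
                              age_group = pr$age_group, treatment = pr$treatment,
                              seed = seed,
                              truth_puncta_count = nrow(tr$puncta),
                              truth_area_ratio = tr$area_ratio_truth,
                              truth_lyso_count = nrow(tr$lysosomes),
                              truth_contact_prob = pr$contact_prob,
                              pixel_size_um = config$pixel_size_um,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (write_files)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  attr(manifest, "truths") <- truths
  if (!write_files) attr(manifest, "images") <- images
  manifest
}
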