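#' Segment the fiber from one channel
#'
#' Gaussian smoothing, Otsu threshold, hole filling, then the largest
#' 8-connected component. The long-axis orientation is estimated from the
#' second moments of the component's pixel coordinates.
#'
#' @param image a [fiber_image()] or plain matrix.
#' @param channel channel to segment on (default `"mito"`, the channel
#'   with the most uniform in-fiber signal).
#' @param min_area_px smallest acceptable component (default 500 px).
#' @param smooth_sigma_px Gaussian smoothing sigma before thresholding.
#' @param refine_angle refine the moment-based orientation by maximizing
#'   the striation contrast of the axial profile (default TRUE). The
#'   moment estimate of a nearly rectangular mask is only good to about a
#'   degree, while striation flattening needs the axis to a fraction of a
#'   degree; the striations themselves are the sharpest orientation cue.
#' @return object of class `fiber_mask`: `mask` (logical raster),
#'   `axis_angle` (degrees, in (-90, 90]), `area_px`, `area_um2`,
#'   `centroid_um` and `pixel_size_um`.
#' @export
segment_fiber <- function(image, channel = "mito", min_area_px = 500,
                          smooth_sigma_px = 1, refine_angle = TRUE) {
  m <- get_channel(image, channel)
  px <- if (inherits(image, "fiber_image")) image$pixel_size_um else
    stop("pass a fiber_image, or use segment_fiber_matrix with pixel size")
  segment_fiber_matrix(m, px, min_area_px, smooth_sigma_px, refine_angle)
}

# magnitude of the Fourier coefficient of the projected intensities at
# the striation frequency; maximal when the projection axis is the true
# fiber axis (any angle error smears the phase across the transverse
# direction and attenuates the coefficient)
.striation_coherence <- function(angle_deg, xs, ys, vals, period_um) {
  th <- angle_deg * pi / 180
  u <- xs * cos(th) + ys * sin(th)
  Mod(sum(vals * exp(2i * pi * u / period_um)))
}

# dominant striation period of a (position, intensity) profile by
# periodogram, searched between min_period and max_period
.dominant_period <- function(position, intensity, min_period = 1,
                             max_period = 4) {
  y <- intensity - mean(intensity)
  n <- length(y)
  if (n < 8) return(NULL)
  h <- position[2] - position[1]
  sp <- Mod(stats::fft(y))[2:floor(n / 2)]
  per <- n * h / seq_along(sp)
  ok <- per >= min_period & per <= max_period
  if (!any(ok)) return(NULL)
  if (max(sp[ok]) < 5 * stats::median(sp)) return(NULL)  # no clear striation
  per[ok][which.max(sp[ok])]
}

#' @rdname segment_fiber
#' @param pixel_size_um pixel size for a bare matrix input.
#' @export
segment_fiber_matrix <- function(image, pixel_size_um, min_area_px = 500,
                                 smooth_sigma_px = 1, refine_angle = TRUE) {
  m <- image
  rng <- range(m)
  if (diff(rng) == 0)
    stop_fiberflux("fiberflux_no_fiber", "image is constant; no fiber found")
  sm <- m
  if (smooth_sigma_px > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(m), sigma = smooth_sigma_px))
  scaled <- (sm - min(sm)) / (max(sm) - min(sm))
  th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
  bw <- scaled > th
  bw <- as.matrix(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  lab <- label_components(bw)
  if (max(lab) == 0)
    stop_fiberflux("fiberflux_no_fiber", "no foreground component found")
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_area_px)
    stop_fiberflux("fiberflux_no_fiber",
                   "largest component has %d px (< %d)", sizes[best], min_area_px)
  mask <- lab == best
  grid <- pixel_grid_um(dim(m), pixel_size_um)
  xs <- grid$x[mask]; ys <- grid$y[mask]
  cx <- mean(xs); cy <- mean(ys)
  cxx <- mean((xs - cx)^2); cyy <- mean((ys - cy)^2)
  cxy <- mean((xs - cx) * (ys - cy))
  angle <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  if (angle <= -90) angle <- angle + 180
  if (angle > 90) angle <- angle - 180
  if (refine_angle) {
    vals <- m[mask]
    # crude axial profile at the moment-based angle, for the period
    th0 <- angle * pi / 180
    u0 <- xs * cos(th0) + ys * sin(th0)
    bin <- floor((u0 - min(u0)) / pixel_size_um)
    prof <- as.numeric(tapply(vals, bin, mean))
    prof <- prof[!is.na(prof)]
    period <- .dominant_period(seq_along(prof) * pixel_size_um, prof)
    if (!is.null(period)) {
      opt <- stats::optimize(.striation_coherence, c(angle - 2, angle + 2),
                             xs = xs, ys = ys, vals = vals,
                             period_um = period, maximum = TRUE, tol = 1e-3)
      if (opt$objective > .striation_coherence(angle, xs, ys, vals, period))
        angle <- opt$maximum
    }
  }
  structure(list(mask = mask, axis_angle = angle,
                 area_px = sum(mask),
                 area_um2 = sum(mask) * pixel_size_um^2,
                 centroid_um = c(cx, cy),
                 pixel_size_um = pixel_size_um),
            class = "fiber_mask")
}

#' @export
print.fiber_mask <- function(x, ...) {
  cat(sprintf("fiber_mask: %d px (%.1f um2), axis angle %.2f deg\n",
              x$area_px, x$area_um2, x$axis_angle))
  invisible(x)
}

#' Axial intensity profile along the fiber long axis
#'
#' In-mask pixels are projected onto the fiber axis and averaged in
#' uniform axial bins (area average, not a line scan). Empty bins at
#' either end are dropped; interior empty bins are linearly interpolated.
#'
#' @param image a [fiber_image()] or matrix.
#' @param mask a [segment_fiber()] result.
#' @param channel channel to profile (ignored for matrix input).
#' @param bin_width_um axial bin width (default = one pixel).
#' @return object of class `axis_profile`: data.frame columns
#'   `position_um` (bin centers, 0 at the first populated bin) and
#'   `intensity`; attributes `bin_width_um`, `origin_u_um` (axial
#'   coordinate of position 0 relative to the mask centroid),
#'   `centroid_um`, `axis_angle_deg`.
#' @export
axis_profile <- function(image, mask, channel = "lc3",
                         bin_width_um = mask$pixel_size_um) {
  stopifnot(inherits(mask, "fiber_mask"), bin_width_um > 0)
  m <- get_channel(image, channel)
  stopifnot(identical(dim(m), dim(mask$mask)))
  grid <- pixel_grid_um(dim(m), mask$pixel_size_um)
  fc <- fiber_frame_coords(grid$x[mask$mask], grid$y[mask$mask],
                           mask$centroid_um, mask$axis_angle)
  u <- fc$u
  vals <- m[mask$mask]
  # round() binning: bin centers sit on multiples of the bin width, so an
  # axis-aligned fiber (u on exact column positions) bins stably
  bin <- round((u - min(u)) / bin_width_um)
  means <- tapply(vals, bin, mean)
  all_bins <- seq(0, max(bin))
  intensity <- rep(NA_real_, length(all_bins))
  intensity[as.integer(names(means)) + 1L] <- means
  populated <- which(!is.na(intensity))
  if (length(populated) < 2L)
    stop_fiberflux("fiberflux_degenerate_profile",
                   "fewer than 2 populated axial bins")
  intensity <- intensity[populated[1]:populated[length(populated)]]
  kept <- all_bins[populated[1]:populated[length(populated)]]
  if (anyNA(intensity)) {
    ok <- !is.na(intensity)
    intensity[!ok] <- stats::approx(kept[ok], intensity[ok], xout = kept[!ok])$y
  }
  centers_u <- min(u) + kept * bin_width_um
  prof <- data.frame(position_um = centers_u - centers_u[1],
                     intensity = as.numeric(intensity))
  structure(prof, class = c("axis_profile", "data.frame"),
            bin_width_um = bin_width_um,
            origin_u_um = centers_u[1],
            centroid_um = mask$centroid_um,
            axis_angle_deg = mask$axis_angle)
}

#' Detect paired mitochondrial peaks in an axial profile
#'
#' Local maxima above median + k * mad with a minimum separation of
#' 0.25 * period are matched into (left, right) pairs. Adjacent peak gaps
#' smaller than 0.75 * period are eligible; pairs are chosen greedily by
#' smallest gap first (each peak used once), which keeps the pairing
#' anchored on the tight intra-pair spacing even when the field of view
#' clips a row at either end. Unpaired peaks are discarded and counted.
#'
#' @param profile an [axis_profile()] of the mitochondrial channel.
#' @param config a [sim_config()] or a list with `sarcomere_period_um`;
#'   may also be a single number giving the expected period in microns.
#' @param k_mad robust height floor multiplier (default 1).
#' @return data.frame with columns `left` and `right` (positions in the
#'   profile's coordinate, microns) and attribute `n_unpaired`; zero rows
#'   when fewer than two maxima are found.
#' @export
detect_mito_pairs <- function(profile, config = 2.0, k_mad = 1) {
  period <- if (is.numeric(config)) config else config$sarcomere_period_um
  pk <- find_profile_peaks(profile$position_um, profile$intensity,
                           k_mad = k_mad, min_sep = 0.25 * period)
  empty <- data.frame(left = numeric(0), right = numeric(0))
  attr(empty, "n_unpaired") <- nrow(pk)
  if (nrow(pk) < 2L) return(keep_frame(empty, profile))
  pos <- sort(pk$position)
  gaps <- diff(pos)
  eligible <- which(gaps < 0.75 * period)
  used <- logical(length(pos))
  pairs <- list()
  for (g in eligible[order(gaps[eligible])]) {
    if (used[g] || used[g + 1]) next
    used[g] <- used[g + 1] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(pos[g], pos[g + 1])
  }
  if (!length(pairs)) return(keep_frame(empty, profile))
  out <- do.call(rbind, pairs)
  out <- data.frame(left = out[, 1], right = out[, 2])
  out <- out[order(out$left), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unpaired") <- sum(!used)
  keep_frame(out, profile)
}

#' @keywords internal
keep_frame <- function(x, profile) {
  for (a in c("origin_u_um", "centroid_um", "axis_angle_deg"))
    attr(x, a) <- attr(profile, a)
  x
}

#' Infer Z-line positions from mitochondrial peak pairs
#'
#' Each Z-line is the arithmetic midpoint of one (left, right) pair of
#' mitochondrial peaks; the sarcomere period is the median successive
#' Z-line difference (NA with fewer than 2 Z-lines).
#'
#' @param pairs a [detect_mito_pairs()] result (>= 1 row).
#' @return object of class `zline_map`: `zline_positions_um` (profile
#'   coordinate), `period_um`, `mito_pair_positions_um`, plus the profile
#'   frame attributes.
#' @export
infer_zlines <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop_fiberflux("fiberflux_empty_zlines", "no mitochondrial pairs to infer Z-lines from")
  z <- sort((pairs$left + pairs$right) / 2)
  period <- if (length(z) >= 2) stats::median(diff(z)) else NA_real_
  structure(list(zline_positions_um = z,
                 period_um = period,
                 mito_pair_positions_um = pairs,
                 origin_u_um = attr(pairs, "origin_u_um"),
                 centroid_um = attr(pairs, "centroid_um"),
                 axis_angle_deg = attr(pairs, "axis_angle_deg")),
            class = "zline_map")
}

#' @export
print.zline_map <- function(x, ...) {
  cat(sprintf("zline_map: %d Z-lines, period %.3f um\n",
              length(x$zline_positions_um), x$period_um))
  invisible(x)
}

#' Mean absolute offset between LC3 profile peaks and the Z-lines
#'
#' For each Z-line, the distance to the nearest LC3 axial-profile maximum;
#' returns the mean absolute distance (microns). Small values indicate the
#' LC3 baseline is striated on the Z-lines.
#'
#' @param lc3_profile an [axis_profile()] of the LC3 channel.
#' @param zmap an [infer_zlines()] result from the same mask.
#' @param k_mad peak height floor multiplier (default 1).
#' @return mean absolute offset in microns.
#' @export
lc3_alignment_offset <- function(lc3_profile, zmap, k_mad = 1) {
  stopifnot(inherits(zmap, "zline_map"), length(zmap$zline_positions_um) >= 1)
  min_sep <- if (is.na(zmap$period_um)) 0 else 0.25 * zmap$period_um
  pk <- find_profile_peaks(lc3_profile$position_um, lc3_profile$intensity,
                           k_mad = k_mad, min_sep = min_sep)
  if (nrow(pk) == 0L)
    stop_fiberflux("fiberflux_no_peaks", "no local maxima in the LC3 profile")
  # compare in absolute axial coordinates in case the two profiles were
  # binned with different origins
  pk_u <- attr(lc3_profile, "origin_u_um") + pk$position
  z_u <- zmap$origin_u_um + zmap$zline_positions_um
  mean(dist_to_nearest_sorted(z_u, sort(pk_u)))
}

#' Absolute axial coordinates of a Z-line map
#'
#' Z-line positions expressed in the fiber-frame axial coordinate relative
#' to the mask centroid (rather than the profile's leftmost bin), which is
#' the frame ground-truth Z-lines are stated in.
#'
#' @param zmap an [infer_zlines()] result.
#' @return numeric vector of axial coordinates (microns).
#' @export
zline_positions_axial <- function(zmap) {
  zmap$origin_u_um + zmap$zline_positions_um
}
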