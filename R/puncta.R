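#' Estimate the fiber background intensity
#'
#' The background is the median intensity over in-mask pixels: robust both
#' to puncta (small area fraction) and to isolated hot pixels.
#'
#' @param image a [fiber_image()] or matrix.
#' @param mask a [segment_fiber()] result (or logical matrix).
#' @param channel channel to use for a `fiber_image` input.
#' @return background level (a.u.).
#' @export
estimate_background <- function(image, mask, channel = "lc3") {
  m <- get_channel(image, channel)
  mk <- if (inherits(mask, "fiber_mask")) mask$mask else mask
  if (!any(mk))
    stop_fiberflux("fiberflux_empty_mask", "mask is empty")
  stats::median(m[mk])
}

#' Remove the striated LC3 baseline before thresholding
#'
#' The LC3 baseline forms a periodic ridge on the Z-lines which would
#' cross an intensity-above-background threshold on its own. A striation
#' template is estimated as the per-axial-bin median intensity (bins of
#' half a pixel in the fiber frame, taken across the transverse
#' direction), linearly interpolated at each pixel's axial coordinate.
#' The template is subtracted and the median of the bin medians - the
#' fiber's background pedestal - is added back, so the flattened image
#' keeps the original background level with the striation modulation
#' removed; values are clamped at 0. Puncta survive because they occupy a
#' small fraction of any axial bin and do not move the bin median.
#'
#' @param image a [fiber_image()] or matrix (LC3 channel).
#' @param mask a [segment_fiber()] result.
#' @param axis_angle fiber orientation in degrees (default: the mask's).
#' @param channel channel for `fiber_image` input.
#' @param bin_width_um axial bin width of the striation template
#'   (default half a pixel; the ridge is near the sampling limit, so the
#'   template must be sampled finer than the raster).
#' @param n_strips number of transverse strips with independent templates
#'   (default 3). The template error from a residual orientation error
#'   grows linearly with the transverse lever arm, so strip-wise templates
#'   keep the ridge flanks flat even when the axis estimate is a tenth of
#'   a degree off.
#' @return flattened intensity matrix (out-of-mask pixels unchanged).
#' @export
flatten_striation <- function(image, mask, axis_angle = mask$axis_angle,
                              channel = "lc3",
                              bin_width_um = 0.5 * mask$pixel_size_um,
                              n_strips = 3) {
  stopifnot(inherits(mask, "fiber_mask"), n_strips >= 1)
  m <- get_channel(image, channel)
  grid <- pixel_grid_um(dim(m), mask$pixel_size_um)
  inm <- mask$mask
  fc <- fiber_frame_coords(grid$x[inm], grid$y[inm], mask$centroid_um, axis_angle)
  vals <- m[inm]
  strip <- ceiling(n_strips * rank(fc$v, ties.method = "first") /
                     length(fc$v))
  flat <- numeric(length(vals))
  pedestals <- numeric(n_strips)
  for (s in seq_len(n_strips)) {
    sel <- strip == s
    u <- fc$u[sel]
    bin <- round((u - min(u)) / bin_width_um)
    med <- tapply(vals[sel], bin, stats::median)
    centers <- as.numeric(names(med)) * bin_width_um + min(u)
    template <- stats::approx(centers, as.numeric(med), xout = u, rule = 2)$y
    pedestals[s] <- stats::median(med)
    flat[sel] <- vals[sel] - template
  }
  # one shared pedestal so the background level stays transversely uniform
  out <- m
  out[inm] <- pmax(flat + stats::median(pedestals), 0)
  out
}

#' Detect autophagosome puncta by intensity above background
#'
#' After striation flattening, the background is re-estimated and pixels
#' strictly brighter than `threshold_factor` times the background (default
#' 1.1, i.e. 10% above the background) form the foreground. 8-connected
#' components smaller than `min_area_px` are discarded. Each record is
#' annotated with its distance to the nearest Z-line and an `off_zline`
#' flag (distance > `zline_band_halfwidth_um`).
#'
#' @param image a [fiber_image()] or matrix.
#' @param mask a [segment_fiber()] result.
#' @param zmap an [infer_zlines()] result, or NULL (then distances are NA
#'   and `off_zline` is TRUE, flagged via the `zline_map_missing`
#'   attribute).
#' @param channel channel to segment.
#' @param threshold_factor multiplicative threshold on the background
#'   (default 1.1).
#' @param min_area_px minimum component area (default 4 px).
#' @param zline_band_halfwidth_um half-width of the on-Z-line band
#'   (default 0.15 um).
#' @param flatten apply [flatten_striation()] first (default TRUE; use
#'   FALSE for channels without a sarcomeric baseline).
#' @return object of class `puncta_set`: `records` data.frame (label,
#'   centroid_x_um, centroid_y_um, centroid_u_um, centroid_v_um, area_px,
#'   area_um2, mean_intensity, dist_to_zline_um, off_zline),
#'   `source_channel`, `background_level`, `threshold_level`, and the
#'   label raster as `labels`.
#' @export
segment_autophagosomes <- function(image, mask, zmap = NULL, channel = "lc3",
                                   threshold_factor = 1.1, min_area_px = 4,
                                   zline_band_halfwidth_um = 0.15,
                                   flatten = TRUE) {
  stopifnot(inherits(mask, "fiber_mask"))
  work <- if (flatten) flatten_striation(image, mask, channel = channel)
          else get_channel(image, channel)
  bg <- estimate_background(work, mask)
  thr <- threshold_factor * bg
  fg <- mask$mask & (work > thr)   # strict inequality
  lab <- label_components(fg)
  n <- max(lab)
  records <- data.frame(label = integer(0), centroid_x_um = numeric(0),
                        centroid_y_um = numeric(0), centroid_u_um = numeric(0),
                        centroid_v_um = numeric(0), area_px = integer(0),
                        area_um2 = numeric(0), mean_intensity = numeric(0),
                        dist_to_zline_um = numeric(0), off_zline = logical(0))
  if (n > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = n)
    keep <- which(sizes >= min_area_px)
    if (length(keep)) {
      px <- mask$pixel_size_um
      grid <- pixel_grid_um(dim(work), px)
      idx <- which(lab > 0 & matrix(lab %in% keep, nrow(lab), ncol(lab)))
      l <- lab[idx]
      cx <- tapply(grid$x[idx], l, mean)
      cy <- tapply(grid$y[idx], l, mean)
      mi <- tapply(work[idx], l, mean)
      fc <- fiber_frame_coords(as.numeric(cx), as.numeric(cy),
                               mask$centroid_um, mask$axis_angle)
      dz <- rep(NA_real_, length(keep))
      if (!is.null(zmap) && length(zmap$zline_positions_um) > 0) {
        z_u <- sort(zline_positions_axial(zmap))
        dz <- dist_to_nearest_sorted(fc$u, z_u)
      }
      off <- if (all(is.na(dz))) rep(TRUE, length(keep))
             else dz > zline_band_halfwidth_um
      # relabel 1..k in raster order
      newlab <- integer(n); newlab[keep] <- seq_along(keep)
      lab[lab > 0] <- newlab[lab[lab > 0]]
      records <- data.frame(label = seq_along(keep),
                            centroid_x_um = as.numeric(cx),
                            centroid_y_um = as.numeric(cy),
                            centroid_u_um = fc$u, centroid_v_um = fc$v,
                            area_px = sizes[keep],
                            area_um2 = sizes[keep] * px^2,
                            mean_intensity = as.numeric(mi),
                            dist_to_zline_um = dz,
                            off_zline = off)
      rownames(records) <- NULL
    } else {
      lab[] <- 0L
    }
  }
  structure(list(records = records, source_channel = channel,
                 background_level = bg, threshold_level = thr,
                 labels = lab, pixel_size_um = mask$pixel_size_um,
                 zline_map_missing = is.null(zmap)),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set (%s): %d objects, background %.1f, threshold %.1f\n",
              x$source_channel, nrow(x$records), x$background_level,
              x$threshold_level))
  invisible(x)
}

#' Autophagosome area ratio of a fiber segment
#'
#' The headline per-fiber statistic: total detected punctum area divided
#' by the area of the imaged fiber segment.
#'
#' @param puncta a [segment_autophagosomes()] result.
#' @param mask the [segment_fiber()] result of the same image.
#' @param off_zline_only when TRUE, only puncta outside the Z-line band
#'   are counted (the morphological definition of an autophagosome); the
#'   default counts every above-threshold punctum.
#' @return ratio in [0, 1].
#' @export
area_ratio <- function(puncta, mask, off_zline_only = FALSE) {
  stopifnot(inherits(puncta, "puncta_set"), inherits(mask, "fiber_mask"))
  if (mask$area_px == 0)
    stop_fiberflux("fiberflux_empty_mask", "mask has zero area")
  rec <- puncta$records
  if (off_zline_only) rec <- rec[rec$off_zline, , drop = FALSE]
  sum(rec$area_px) / mask$area_px
}
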