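#' Extract a lane profile from a blot image
#'
#' Sums intensity across the lane width for each migration row. When the
#' image shows dark bands on a light background (detected by comparing the
#' lane-box mean to the whole-image median, overridable via `invert`), the
#' image is inverted first so bands are positive peaks.
#'
#' @param blot_image numeric matrix (grayscale blot; rows = migration
#'   coordinate).
#' @param lane_box integer vector `c(row_start, row_end, col_start,
#'   col_end)` delimiting the lane.
#' @param invert TRUE/FALSE to force polarity; NULL (default) auto-detect.
#' @param lane_id optional label.
#' @return object of class `lane_profile`: data.frame with `position_px`
#'   and `intensity`, attributes `lane_id` and `inverted`.
#' @export
lane_profile <- function(blot_image, lane_box, invert = NULL, lane_id = NULL) {
  stopifnot(is.matrix(blot_image), length(lane_box) == 4)
  r1 <- lane_box[1]; r2 <- lane_box[2]; c1 <- lane_box[3]; c2 <- lane_box[4]
  if (r1 < 1 || c1 < 1 || r2 > nrow(blot_image) || c2 > ncol(blot_image) ||
      r1 > r2 || c1 > c2)
    stop_fiberflux("fiberflux_bad_box", "lane_box is degenerate or outside the image")
  box <- blot_image[r1:r2, c1:c2, drop = FALSE]
  if (is.null(invert)) invert <- mean(box) < stats::median(blot_image)
  if (invert) box <- max(blot_image) - box
  prof <- data.frame(position_px = r1:r2, intensity = rowSums(box))
  structure(prof, class = c("lane_profile", "data.frame"),
            lane_id = lane_id, inverted = invert)
}

#' Integrated, baseline-subtracted band intensity
#'
#' The baseline is the straight line joining the profile values at the two
#' window endpoints; the integrated intensity is the sum of
#' (intensity - baseline) over the window, clamped at 0. Windows should
#' include a flanking baseline point on each side of the band.
#'
#' @param profile a [lane_profile()] (or data.frame with `position_px`
#'   and `intensity`).
#' @param window_px integer vector `c(start, end)` in profile positions.
#' @param band_id optional protein label (e.g. "cleaved-caspase-3",
#'   "tubulin").
#' @return object of class `band_measurement`: `band_id`, `window_px`,
#'   `integrated_intensity`.
#' @export
quantify_band <- function(profile, window_px, band_id = NULL) {
  pos <- profile$position_px
  i1 <- match(window_px[1], pos); i2 <- match(window_px[2], pos)
  if (is.na(i1) || is.na(i2) || i1 > i2)
    stop_fiberflux("fiberflux_bad_window", "window [%s, %s] outside profile",
                   window_px[1], window_px[2])
  y <- profile$intensity[i1:i2]
  baseline <- seq(y[1], y[length(y)], length.out = length(y))
  structure(list(band_id = band_id, window_px = window_px,
                 integrated_intensity = max(sum(y - baseline), 0)),
            class = "band_measurement")
}

#' @export
print.band_measurement <- function(x, ...) {
  cat(sprintf("band %s [%d, %d]: %.2f\n",
              if (is.null(x$band_id)) "?" else x$band_id,
              x$window_px[1], x$window_px[2], x$integrated_intensity))
  invisible(x)
}

#' @keywords internal
band_value <- function(x) {
  if (inherits(x, "band_measurement")) x$integrated_intensity else as.numeric(x)
}

#' Band intensity relative to the loading control
#'
#' @param band a [quantify_band()] result (or a number).
#' @param loading the loading-control band (tubulin); must be positive.
#' @return dimensionless ratio.
#' @export
relative_intensity <- function(band, loading) {
  l <- band_value(loading)
  if (!is.finite(l) || l <= 0)
    stop_fiberflux("fiberflux_zero_loading",
                   "loading-control signal is zero or negative")
  band_value(band) / l
}

#' Cleaved-to-pro band ratio
#'
#' Ratio of two bands of the same protein, e.g. cleaved / pro caspase-3
#' or p-mTOR / mTOR.
#'
#' @param cleaved,pro band measurements (or numbers); `pro` must be
#'   positive.
#' @return dimensionless ratio.
#' @export
cleavage_ratio <- function(cleaved, pro) {
  p <- band_value(pro)
  if (!is.finite(p) || p <= 0)
    stop_fiberflux("fiberflux_zero_loading", "denominator band is zero or negative")
  band_value(cleaved) / p
}

#' Render a synthetic blot image with Gaussian bands
#'
#' For testing and demonstration: lanes are vertical strips, each band a
#' Gaussian in the migration (row) direction with the given integrated
#' area, on a flat background with optional Gaussian noise.
#'
#' @param n_rows,n_cols image size.
#' @param lanes list of lanes; each lane is a list with `cols = c(c1, c2)`
#'   and `bands = data.frame(center_row, sigma_px, area)` (area is the
#'   target integrated intensity per column).
#' @param background flat background level.
#' @param noise_sd Gaussian noise sd (0 = none).
#' @param seed optional seed for the noise.
#' @return numeric matrix.
#' @export
simulate_blot_image <- function(n_rows, n_cols, lanes, background = 100,
                                noise_sd = 0, seed = NULL) {
  img <- matrix(background, n_rows, n_cols)
  rows <- seq_len(n_rows)
  for (lane in lanes) {
    cols <- lane$cols[1]:lane$cols[2]
    prof <- rep(0, n_rows)
    for (i in seq_len(nrow(lane$bands))) {
      b <- lane$bands[i, ]
      prof <- prof + b$area / (b$sigma_px * sqrt(2 * pi)) *
        exp(-(rows - b$center_row)^2 / (2 * b$sigma_px^2))
    }
    img[, cols] <- img[, cols] + prof
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) withr::local_seed(as.integer(seed))
    img <- img + matrix(stats::rnorm(n_rows * n_cols, 0, noise_sd), n_rows, n_cols)
  }
  img
}
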