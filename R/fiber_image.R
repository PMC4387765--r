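#' Multi-channel fiber image container
#'
#' A `fiber_image` holds the three confocal channels of one imaged fiber
#' segment as base-R matrices on a 16-bit arbitrary-unit intensity scale,
#' together with the pixel size and condition metadata.
#'
#' @param channels named list of numeric matrices with identical
#'   dimensions; canonical names are `lc3` (LC3-RFP), `mito`
#'   (MitoTracker) and `lyso` (LysoTracker).
#' @param pixel_size_um pixel side length in microns.
#' @param condition optional named list or character giving condition
#'   labels (genotype, age_group, treatment).
#' @param metadata optional named list of extra per-image metadata.
#' @return object of class `fiber_image`.
#' @export
fiber_image <- function(channels, pixel_size_um, condition = NULL,
                        metadata = list()) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), pixel_size_um > 0)
  d <- dim(channels[[1]])
  for (ch in channels) {
    if (!is.matrix(ch) || !identical(dim(ch), d))
      stop("all channels must be matrices with identical dimensions")
  }
  structure(list(channels = channels,
                 pixel_size_um = pixel_size_um,
                 condition = condition,
                 metadata = metadata),
            class = "fiber_image")
}

#' @export
print.fiber_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("fiber_image: %d x %d px (%.1f x %.1f um), channels: %s\n",
              d[1], d[2], d[1] * x$pixel_size_um, d[2] * x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$condition))
    cat("  condition:", paste(unlist(x$condition), collapse = " / "), "\n")
  invisible(x)
}

#' @export
dim.fiber_image <- function(x) dim(x$channels[[1]])

#' @keywords internal
get_channel <- function(image, channel) {
  if (is.matrix(image)) return(image)
  stopifnot(inherits(image, "fiber_image"))
  if (!channel %in% names(image$channels))
    stop_fiberflux("fiberflux_bad_channel", "channel '%s' not present (have: %s)",
                   channel, paste(names(image$channels), collapse = ", "))
  image$channels[[channel]]
}

#' Write a fiber image as a 16-bit multi-page TIFF
#'
#' Page order is the order of the channel list (canonically lc3, mito,
#' lyso). Intensities are rounded to integers and clipped to [0, 65535].
#'
#' @param image a [fiber_image()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fiber_tiff <- function(image, path) {
  stopifnot(inherits(image, "fiber_image"))
  pages <- lapply(image$channels, function(ch)
    pmin(pmax(round(ch), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_fiber_tiff()]
#'
#' @param path TIFF file path.
#' @param pixel_size_um pixel size in microns (TIFFs carry no calibrated
#'   pixel size here; cohorts record it in their manifest).
#' @param channel_names names for the pages, by position.
#' @param condition optional condition metadata to attach.
#' @return a [fiber_image()] with intensities on the original 16-bit scale.
#' @export
read_fiber_tiff <- function(path, pixel_size_um,
                            channel_names = c("lc3", "mito", "lyso"),
                            condition = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  chans <- lapply(pages, function(p) round(p * 65535))
  names(chans) <- channel_names[seq_along(chans)]
  fiber_image(chans, pixel_size_um, condition = condition,
              metadata = list(file = path))
}
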