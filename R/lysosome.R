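#' Detect lysosome puncta
#'
#' Same threshold / connectivity / minimum-area machinery as
#' [segment_autophagosomes()], applied to the lysosome channel without
#' striation flattening (lysosomes have no sarcomeric baseline). The
#' threshold factor defaults to the same 1.1 but can be overridden since
#' LysoTracker background differs from LC3-RFP.
#'
#' @inheritParams segment_autophagosomes
#' @return a `puncta_set` of lysosome objects.
#' @export
segment_lysosomes <- function(image, mask, channel = "lyso",
                              threshold_factor = 1.1, min_area_px = 4) {
  segment_autophagosomes(image, mask, zmap = NULL, channel = channel,
                         threshold_factor = threshold_factor,
                         min_area_px = min_area_px, flatten = FALSE)
}

#' Count lysosomes and classify high-lysosome fibers
#'
#' A fiber is "high-lysosome" when it contains strictly more than
#' `high_threshold` (default 100) detected lysosome puncta in the imaged
#' segment; a fiber with exactly 100 is not high.
#'
#' @param lyso a [segment_lysosomes()] result.
#' @param high_threshold classification cut (default 100).
#' @return object of class `lysosome_result`: `count`, `is_high`.
#' @export
count_and_classify <- function(lyso, high_threshold = 100) {
  stopifnot(inherits(lyso, "puncta_set"))
  count <- nrow(lyso$records)
  structure(list(count = count, is_high = count > high_threshold,
                 high_threshold = high_threshold),
            class = "lysosome_result")
}

#' @export
print.lysosome_result <- function(x, ...) {
  cat(sprintf("lysosome_result: %d lysosomes, high (> %d): %s\n",
              x$count, x$high_threshold, x$is_high))
  invisible(x)
}

#' Percentage of high-lysosome fibers in a group
#'
#' @param results list of [count_and_classify()] results, or a logical
#'   vector of per-fiber `is_high` flags.
#' @return percentage in [0, 100].
#' @export
percent_high <- function(results) {
  flags <- if (is.logical(results)) results
           else vapply(results, function(r) r$is_high, logical(1))
  if (length(flags) == 0L)
    stop_fiberflux("fiberflux_empty_group", "no fibers in group")
  100 * mean(flags)
}

#' Boundary gap (in pixels) from each labeled object to a foreground set
#'
#' Pixels are unit squares; the boundary-to-boundary distance between two
#' pixels with center offsets (dx, dy) is
#' sqrt(max(0, |dx| - 1)^2 + max(0, |dy| - 1)^2), which is 0 exactly when
#' the squares overlap or touch (8-adjacency).
#' @keywords internal
object_min_gaps_px <- function(labels_a, fg_b) {
  n <- max(labels_a)
  if (n == 0L) return(numeric(0))
  nr <- nrow(labels_a)
  bidx <- which(fg_b)
  if (length(bidx) == 0L) return(rep(Inf, n))
  br <- (bidx - 1L) %% nr; bc <- (bidx - 1L) %/% nr
  aidx <- which(labels_a > 0)
  ar <- (aidx - 1L) %% nr; ac <- (aidx - 1L) %/% nr
  lab <- labels_a[aidx]
  gaps <- rep(Inf, n)
  for (l in seq_len(n)) {
    sel <- lab == l
    dr <- pmax(abs(outer(ar[sel], br, "-")) - 1, 0)
    dc <- pmax(abs(outer(ac[sel], bc, "-")) - 1, 0)
    gaps[l] <- sqrt(min(dr * dr + dc * dc))
  }
  gaps
}

#' Fraction of LC3 puncta in contact with a lysosome
#'
#' An LC3 punctum is "in contact" when its minimum boundary-to-boundary
#' pixel distance to any lysosome is at most `max_gap_um` (default 0.4 um,
#' two pixels at the default scale). Pixels are treated as unit squares,
#' so overlapping or 8-adjacent objects have gap 0.
#'
#' @param lc3 a [segment_autophagosomes()] result.
#' @param lyso a [segment_lysosomes()] result on the same image frame.
#' @param max_gap_um contact distance (microns).
#' @return contacting fraction in [0, 1]; `NA` when there are no LC3
#'   puncta. The per-punctum gaps are attached as attribute `gaps_um`.
#' @export
contact_fraction <- function(lc3, lyso, max_gap_um = 0.4) {
  stopifnot(inherits(lc3, "puncta_set"), inherits(lyso, "puncta_set"))
  if (!identical(dim(lc3$labels), dim(lyso$labels)))
    stop_fiberflux("fiberflux_geometry_mismatch",
                   "LC3 and lysosome sets come from different image geometries")
  n_lc3 <- nrow(lc3$records)
  if (n_lc3 == 0L) return(NA_real_)
  if (nrow(lyso$records) == 0L) {
    out <- 0
    attr(out, "gaps_um") <- rep(Inf, n_lc3)
    return(out)
  }
  gaps_um <- object_min_gaps_px(lc3$labels, lyso$labels > 0) * lc3$pixel_size_um
  out <- mean(gaps_um <= max_gap_um)
  attr(out, "gaps_um") <- gaps_um
  out
}
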