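#' @keywords internal
"_PACKAGE"

#' Pixel-center coordinates of a raster, in microns
#'
#' Pixels are addressed row-major with a pixel-center convention: pixel
#' (r, c) (1-based) has coordinates x = (c - 0.5) * pixel_size,
#' y = (r - 0.5) * pixel_size, with y increasing down the rows.
#'
#' @param shape integer vector (rows, cols).
#' @param pixel_size_um length of a pixel side in microns.
#' @return list with matrices `x` and `y` of dimension `shape`.
#' @keywords internal
pixel_grid_um <- function(shape, pixel_size_um) {
  nr <- shape[1]; nc <- shape[2]
  x <- matrix(rep((seq_len(nc) - 0.5) * pixel_size_um, each = nr), nr, nc)
  y <- matrix(rep((seq_len(nr) - 0.5) * pixel_size_um, times = nc), nr, nc)
  list(x = x, y = y)
}

#' Project points into a fiber-frame coordinate system
#'
#' The fiber frame is centered at `centroid_um` with its u-axis along the
#' fiber long axis (`angle_deg`, counter-clockwise from the image x-axis in
#' a y-down raster) and its v-axis transverse to it.
#'
#' @param x_um,y_um point coordinates in microns (image frame).
#' @param centroid_um numeric length-2, (x, y) of the frame origin.
#' @param angle_deg axis orientation in degrees.
#' @return list with numeric vectors `u` (axial) and `v` (transverse).
#' @export
fiber_frame_coords <- function(x_um, y_um, centroid_um, angle_deg) {
  th <- angle_deg * pi / 180
  dx <- x_um - centroid_um[1]
  dy <- y_um - centroid_um[2]
  list(u = dx * cos(th) + dy * sin(th),
       v = -dx * sin(th) + dy * cos(th))
}

#' 8-connected labeling of a binary raster
#'
#' Connected components of the foreground under 8-connectivity (edge or
#' corner adjacency). EBImage's bwlabel is 4-connected, so components are
#' built as an igraph over foreground pixels.
#'
#' @param fg logical (or 0/1) matrix.
#' @return integer matrix of the same dimension; 0 is background, labels
#'   are 1..n in order of first (column-major) occurrence.
#' @export
label_components <- function(fg) {
  fg <- fg != 0
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  ef <- integer(0); et <- integer(0)
  # neighbors: down, right, down-right, up-right (covers all 8-adjacency once)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- pos[nb] > 0L
    ef <- c(ef, pos[idx[ok]][hit])
    et <- c(et, pos[nb][hit])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ef)) g <- igraph::add_edges(g, rbind(ef, et))
  memb <- igraph::components(g)$membership
  # relabel in order of first occurrence (column-major scan)
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relab[memb]
  lab
}

#' Distance from each query to the nearest value in a sorted vector
#' @param u numeric queries.
#' @param z sorted numeric vector (length >= 1).
#' @return numeric vector of distances; also attribute-free nearest values
#'   available via `nearest_sorted`.
#' @keywords internal
dist_to_nearest_sorted <- function(u, z) {
  n <- length(z)
  if (n == 0L) return(rep(NA_real_, length(u)))
  i <- findInterval(u, z)
  left <- z[pmax(i, 1L)]
  right <- z[pmin(i + 1L, n)]
  pmin(abs(u - left), abs(u - right))
}

#' @keywords internal
nearest_sorted <- function(u, z) {
  n <- length(z)
  i <- findInterval(u, z)
  left <- z[pmax(i, 1L)]
  right <- z[pmin(i + 1L, n)]
  ifelse(abs(u - left) <= abs(u - right), left, right)
}

#' Local maxima of a 1-D profile with a robust height floor
#'
#' A sample is a peak when it strictly exceeds its left neighbor, is at
#' least its right neighbor, and exceeds median + k_mad * MAD of the
#' whole profile (plain median absolute deviation, no consistency
#' scaling). Peaks closer than `min_sep` keep only the higher one. Peak
#' positions are refined by a three-point parabolic fit (sub-bin accuracy).
#'
#' @param positions numeric, strictly increasing, uniform spacing.
#' @param intensity numeric, same length.
#' @param k_mad multiplier on mad() above the median (default 1).
#' @param min_sep minimum separation between kept peaks, same units as
#'   `positions` (default 0 = keep all).
#' @return data.frame with `position` (refined) and `height`, ordered by
#'   position; zero rows when no peak qualifies.
#' @export
find_profile_peaks <- function(positions, intensity, k_mad = 1, min_sep = 0) {
  n <- length(intensity)
  if (n < 3L) return(data.frame(position = numeric(0), height = numeric(0)))
  floor_level <- stats::median(intensity) +
    k_mad * stats::mad(intensity, constant = 1)
  i <- 2:(n - 1)
  is_peak <- intensity[i] > intensity[i - 1] & intensity[i] >= intensity[i + 1] &
    intensity[i] > floor_level
  cand <- i[is_peak]
  if (length(cand) == 0L) return(data.frame(position = numeric(0), height = numeric(0)))
  # enforce separation, highest first
  keep <- logical(length(cand))
  ord <- order(intensity[cand], decreasing = TRUE)
  kept_pos <- numeric(0)
  for (j in ord) {
    p <- positions[cand[j]]
    if (!length(kept_pos) || min(abs(kept_pos - p)) >= min_sep) {
      keep[j] <- TRUE
      kept_pos <- c(kept_pos, p)
    }
  }
  cand <- sort(cand[keep])
  dp <- positions[2] - positions[1]
  pos <- vapply(cand, function(k) {
    y0 <- intensity[k - 1]; y1 <- intensity[k]; y2 <- intensity[k + 1]
    den <- y0 - 2 * y1 + y2
    off <- if (den < 0) 0.5 * (y0 - y2) / den else 0
    positions[k] + max(-0.5, min(0.5, off)) * dp
  }, numeric(1))
  data.frame(position = pos, height = intensity[cand])
}

#' @keywords internal
stop_fiberflux <- function(class, msg, ...) {
  stop(structure(class = c(class, "fiberflux_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
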