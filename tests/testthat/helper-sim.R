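# shared fixtures: everything is generated in code at test time

# noise-free configuration with the default geometry
noisefree_config <- function(...) {
  fiberflux::sim_config(shot_noise = FALSE, read_noise_sd = 0, ...)
}

# small, fast geometry for pipeline-level tests
small_config <- function(...) {
  fiberflux::sim_config(image_shape = c(96L, 200L), fiber_width_um = 12,
                        fiber_length_um = 32, ...)
}

# wrap a plain logical matrix as a fiber_mask (axis along the columns)
make_mask <- function(mask, pixel_size_um = 0.2, axis_angle = 0) {
  grid <- fiberflux:::pixel_grid_um(dim(mask), pixel_size_um)
  structure(list(mask = mask, axis_angle = axis_angle,
                 area_px = sum(mask),
                 area_um2 = sum(mask) * pixel_size_um^2,
                 centroid_um = c(mean(grid$x[mask]), mean(grid$y[mask])),
                 pixel_size_um = pixel_size_um),
            class = "fiber_mask")
}

# rectangular mask occupying rows r1:r2, cols c1:c2
rect_mask <- function(nr, nc, r1, r2, c1, c2, pixel_size_um = 0.2) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  make_mask(m, pixel_size_um)
}

# a profile-like data.frame with the frame attributes axis_profile sets
fake_profile <- function(position_um, intensity) {
  structure(data.frame(position_um = position_um, intensity = intensity),
            class = c("axis_profile", "data.frame"),
            bin_width_um = position_um[2] - position_um[1],
            origin_u_um = 0, centroid_um = c(0, 0), axis_angle_deg = 0)
}

# project the ground-truth Z-lines of a simulated fiber into the frame of
# a measured mask, and return signed offsets to the nearest measured Z-line
zline_offsets <- function(sim, mask, zmap) {
  tr <- sim$truth
  th <- tr$axis_angle * pi / 180
  zx <- tr$center_um[1] + tr$zline_positions_um * cos(th)
  zy <- tr$center_um[2] + tr$zline_positions_um * sin(th)
  fc <- fiberflux::fiber_frame_coords(zx, zy, mask$centroid_um, mask$axis_angle)
  zu <- sort(fiberflux::zline_positions_axial(zmap))
  vapply(fc$u, function(u) zu[which.min(abs(zu - u))] - u, numeric(1))
}

# replace the sampled objects of a truth with a hand-placed punctum list
# (data.frame with u_um, v_um, radius_um, off_zline); truth must have been
# sampled with axis_angle_range_deg = c(0, 0) so u/v align with x/y
place_puncta <- function(truth, puncta) {
  stopifnot(truth$axis_angle == 0)
  puncta$x_um <- truth$center_um[1] + puncta$u_um
  puncta$y_um <- truth$center_um[2] + puncta$v_um
  truth$puncta <- puncta
  truth
}

# a lane_profile-like object from a plain intensity vector
fake_lane <- function(y) {
  structure(data.frame(position_px = seq_along(y), intensity = y),
            class = c("lane_profile", "data.frame"),
            lane_id = "test", inverted = FALSE)
}

# minimal puncta_set with n records (for the counting/classification API)
fake_lyso_set <- function(n) {
  structure(list(records = data.frame(label = seq_len(n)),
                 source_channel = "lyso", background_level = 0,
                 threshold_level = 0, labels = matrix(0L, 1, 1),
                 pixel_size_um = 0.2),
            class = "puncta_set")
}
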