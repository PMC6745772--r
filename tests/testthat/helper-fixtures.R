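# Shared fixtures: small synthetic scans and hand-built pipeline objects.

# canonical phantom matching the package's study conditions
default_kin <- function(...) annulus_kinematics(...)

# noise-free uniform-inflation phantom (lambda_peak = 1.1), no bulk motion
uniform_sim <- function(A = 0.10, translation = c(0, 0), noise_sd = 0, seed = 1) {
  render_dense_series(
    annulus_kinematics(stretch_amplitude = A, heterogeneity = 0,
                       translation = translation),
    noise_sd = noise_sd, seed = seed)
}

# concentric-circle contours replicated over frames
circle_contours <- function(r_in = 7, r_out = 9, center = c(24, 24),
                            n_frames = 18L, n_pts = 96L) {
  th <- 2 * pi * (seq_len(n_pts) - 1L) / n_pts
  mk <- function(r) cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  wall_contours(rep(list(mk(r_in)), n_frames), rep(list(mk(r_out)), n_frames))
}

# minimal sector_strain_map for the metrics layer: strain = sectors x frames
make_map <- function(strain, valid = rep(TRUE, nrow(strain)),
                     location = "DTA", avi_angle = 0) {
  ns <- nrow(strain)
  structure(list(strain = strain, E_rr = strain * 0, E_rt = strain * 0,
                 valid = valid,
                 sector_centers = (seq_len(ns) - 0.5) * 2 * pi / ns,
                 avi_angle = avi_angle, avi_sector_offset = 0L,
                 n_valid = sum(valid), n_sectors = ns,
                 centroid = c(0, 0), location = location, smoothed = FALSE),
            class = "sector_strain_map")
}

# minimal trajectory_field with given reference points and displacement array
make_traj <- function(X1, U) {
  structure(list(X1 = X1, ij = cbind(seq_len(nrow(X1)), 1L), U = U,
                 n_frames = dim(U)[3]),
            class = "trajectory_field")
}

# one frame of a back-displacement field on an integer voxel lattice
make_back_frame <- function(ij, d, voxel = 1) {
  list(ij = ij,
       pos = cbind((ij[, 2] - 0.5) * voxel, (ij[, 1] - 0.5) * voxel),
       d = d)
}

circ_dist <- function(a, b, n = 16) { d <- abs(a - b) %% n; pmin(d, n - d) }
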