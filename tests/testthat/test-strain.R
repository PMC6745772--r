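# Finite-element Green strain, cylindrical rotation, sector map assembly.

unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("element strain matches hand-computed tensors exactly", {
  expect_equal(green_strain_element(unit_square, 0 * unit_square)$E,
               matrix(0, 2, 2), tolerance = 1e-15)
  # uniform 10% biaxial stretch: E = 0.105 I
  expect_equal(green_strain_element(unit_square, 0.1 * unit_square)$E,
               0.105 * diag(2), tolerance = 1e-12)
  # simple shear H = [[0, 0.2], [0, 0]]: E = [[0, 0.1], [0.1, 0.02]]
  H <- matrix(c(0, 0, 0.2, 0), 2, 2)
  u <- t(H %*% t(unit_square))
  expect_equal(green_strain_element(unit_square, u)$E,
               matrix(c(0, 0.1, 0.1, 0.02), 2, 2), tolerance = 1e-12)
  expect_error(green_strain_element(unit_square[c(1, 2, 1, 2), ], 0 * unit_square),
               "degenerate")
})

test_that("element strain is exact for affine motion regardless of node geometry", {
  set.seed(5)
  for (i in 1:20) {
    nodes <- unit_square * 3 + matrix(rnorm(8, 0, 0.3), 4, 2)
    A <- matrix(rnorm(4, 0, 0.1), 2, 2)
    u <- t(A %*% t(nodes)) + matrix(c(1, -2), 4, 2, byrow = TRUE)
    E_expect <- (A + t(A) + t(A) %*% A) / 2
    expect_equal(green_strain_element(nodes, u)$E, E_expect, tolerance = 1e-10)
  }
})

test_that("cylindrical rotation preserves trace and determinant and aligns with the axes", {
  E <- matrix(c(0.11, 0.03, 0.03, 0.05), 2, 2)
  for (a in c(0, 0.7, -2.1, pi)) {
    rc <- rotate_to_cylindrical(E, a)
    expect_equal(sum(diag(rc$E_cyl)), sum(diag(E)), tolerance = 1e-12)
    expect_equal(det(rc$E_cyl), det(E), tolerance = 1e-12)
  }
  # rotation by 2*pi is the identity on components
  expect_equal(rotate_to_cylindrical(E, 0.3 + 2 * pi)$E_cyl,
               rotate_to_cylindrical(E, 0.3)$E_cyl, tolerance = 1e-12)
  # point on the +x axis of a centered annulus: tangent along -y (image), E_tt = E_yy
  rc <- rotate_to_cylindrical(E, -pi / 2)
  expect_equal(rc$E_tt, E[2, 2], tolerance = 1e-14)
  expect_equal(rc$E_rr, E[1, 1], tolerance = 1e-14)
})

test_that("a well-sampled annulus yields 16 valid sectors with lattice-symmetric nodes", {
  sim <- uniform_sim()
  traj <- track_forward(decode_series(sim$series, sim$contours))
  el <- build_sector_elements(traj, sim$contours)
  expect_true(all(vapply(el$sectors, `[[`, logical(1), "valid")))
  expect_equal(el$centroid, c(24, 24), tolerance = 0.05)
  # the voxel lattice is symmetric under 90 degree rotation about the center,
  # so sector s + 4 nodes are the rotation of sector s nodes
  rot90 <- function(P) cbind(24 + (P[, 2] - 24), 24 - (P[, 1] - 24))
  for (s in 1:4) {
    a <- el$sectors[[s]]$nodes_ref
    b <- el$sectors[[s + 4]]$nodes_ref
    expect_equal(sort(rot90(a)[, 1]), sort(b[, 1]), tolerance = 1e-9)
    expect_equal(sort(rot90(a)[, 2]), sort(b[, 2]), tolerance = 1e-9)
  }
})

test_that("an emptied sector is flagged invalid without disturbing its neighbors", {
  sim <- uniform_sim()
  traj <- track_forward(decode_series(sim$series, sim$contours))
  th <- aortadense:::.anat_angle(traj$X1[, 1] - 24, traj$X1[, 2] - 24)
  keep <- aortadense:::.sector_bin(th, 16) != 3L
  traj2 <- traj; traj2$X1 <- traj$X1[keep, ]; traj2$ij <- traj$ij[keep, ]
  traj2$U <- traj$U[keep, , , drop = FALSE]
  expect_warning(el <- build_sector_elements(traj2, sim$contours), "invalid")
  valid <- vapply(el$sectors, `[[`, logical(1), "valid")
  expect_false(valid[3])
  expect_equal(sum(valid), 15L)
  el_full <- build_sector_elements(traj, sim$contours)
  expect_equal(el$sectors[[10]]$nodes_ref, el_full$sectors[[10]]$nodes_ref)
})

test_that("scans with too many invalid sectors are rejected as poor quality", {
  sim <- uniform_sim()
  traj <- track_forward(decode_series(sim$series, sim$contours))
  th <- aortadense:::.anat_angle(traj$X1[, 1] - 24, traj$X1[, 2] - 24)
  keep <- !aortadense:::.sector_bin(th, 16) %in% 1:6
  traj$X1 <- traj$X1[keep, ]; traj$ij <- traj$ij[keep, ]
  traj$U <- traj$U[keep, , , drop = FALSE]
  suppressWarnings(el <- build_sector_elements(traj, sim$contours))
  expect_error(assemble_sector_map(el), "quality")
})

test_that("AVI renumbering: boundary belongs clockwise and a one-sector AVI shift rotates all labels by one", {
  sim <- render_dense_series(annulus_kinematics(heterogeneity = 0.4,
                                                peak_angle = 4.5 * 2 * pi / 16),
                             noise_sd = 0, seed = 2)
  traj <- track_forward(decode_series(sim$series, sim$contours))
  el <- build_sector_elements(traj, sim$contours)
  w <- 2 * pi / 16
  m0 <- assemble_sector_map(el, avi_angle = 0, strain_smooth = FALSE)
  m_in <- assemble_sector_map(el, avi_angle = w / 3, strain_smooth = FALSE)
  m1 <- assemble_sector_map(el, avi_angle = w, strain_smooth = FALSE)
  # an AVI exactly on a bin boundary starts numbering at the next CCW bin
  expect_equal(m0$strain, m_in$strain)
  expect_equal(m0$avi_sector_offset, 0L)
  expect_equal(m1$avi_sector_offset, 1L)
  # shifting the AVI by one sector width rotates labels by exactly one
  expect_equal(m1$strain[1:15, ], m0$strain[2:16, ], ignore_attr = TRUE)
  expect_equal(m1$strain[16, ], m0$strain[1, ], ignore_attr = TRUE)
})

test_that("pipeline strain matches the finite-difference oracle across stretch and heterogeneity", {
  # interpolation bias of the 3-nearest tracking grows with amplitude;
  # the elements themselves are exact (see objectivity / affine tests)
  for (h in c(0, 0.2, 0.4)) for (A in c(0.05, 0.10, 0.15)) {
    kin <- annulus_kinematics(stretch_amplitude = A, heterogeneity = h,
                              peak_angle = pi / 2)
    sim <- render_dense_series(kin, noise_sd = 0, seed = 1)
    fit <- dense_strain(sim$series, sim$contours, location = "DTA",
                        temporal_window = 1)
    tr <- true_sector_strain(kin)[, kin$t_peak]
    tol <- if (A <= 0.10) 0.01 else 0.02
    expect_lt(max(abs(fit$map$strain[, fit$summary$systole_frame] - tr)), tol)
    if (h > 0) {
      pk <- which.max(fit$map$strain[, fit$summary$systole_frame])
      expect_lte(circ_dist(pk, which.max(tr)), 1)
    }
  }
})

test_that("uniform inflation recovers E_tt = 0.105 with vanishing shear in every sector", {
  sim <- uniform_sim()
  fit <- dense_strain(sim$series, sim$contours, location = "DTA", temporal_window = 1)
  s <- fit$map$strain[, fit$summary$systole_frame]
  expect_true(all(abs(s - 0.105) < 0.005))
  expect_true(all(abs(fit$map$E_rt[, fit$summary$systole_frame]) < 0.01))
})
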