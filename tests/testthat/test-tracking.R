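# Phase unwrapping, displacement decoding (d = phi / 2 pi ke), tracking.

test_that("masked unwrapping returns constant fields unchanged and recovers a wrapped ramp exactly", {
  unwrapm <- aortadense:::.unwrap_masked
  mask <- matrix(TRUE, 12, 30)
  q <- matrix(1, 12, 30); q[1, 1] <- 2   # deterministic seed voxel
  const <- matrix(0.7, 12, 30)
  expect_equal(unwrapm(const, mask, q)$phi, rep(0.7, 360))

  ramp <- matrix(rep(seq(0, 2.2 * pi, length.out = 30), each = 12), 12, 30)
  wrapped <- aortadense:::.wrap_phase(ramp)
  uw <- unwrapm(wrapped, mask, q)
  expect_lt(max(abs(uw$phi - ramp[which(mask)])), 1e-9)
})

test_that("unwrapping a noisy wrapped ramp never commits a 2pi-level error (100 seeds)", {
  unwrapm <- aortadense:::.unwrap_masked
  mask <- matrix(TRUE, 10, 25)
  q <- matrix(1, 10, 25); q[1, 1] <- 2
  ramp <- matrix(rep(seq(0, 2.2 * pi, length.out = 25), each = 10), 10, 25)
  set.seed(2024)
  for (i in 1:100) {
    noisy <- aortadense:::.wrap_phase(ramp + rnorm(250, 0, 0.1))
    uw <- unwrapm(noisy, mask, q)
    expect_lt(max(abs(uw$phi - ramp[which(mask)])), pi)
  }
})

test_that("unwrap restricted to the wall leaves no neighbor jump above pi and errors on an empty mask", {
  sim <- render_dense_series(annulus_kinematics(), noise_sd = 0.05, seed = 5)
  uw <- unwrap_phase(sim$series, sim$contours, t = 8)
  H <- dim(sim$series)[1]
  key <- uw$ij[, 1] + H * uw$ij[, 2]
  for (ch in 1:2) {
    lut <- setNames(uw$phi[, ch], key)
    right <- lut[as.character(uw$ij[, 1] + H * (uw$ij[, 2] + 1))]
    down <- lut[as.character(uw$ij[, 1] + 1 + H * uw$ij[, 2])]
    expect_true(all(abs(uw$phi[, ch] - right) <= pi + 1e-9, na.rm = TRUE))
    expect_true(all(abs(uw$phi[, ch] - down) <= pi + 1e-9, na.rm = TRUE))
  }
  shrunk <- circle_contours(r_in = 0.2, r_out = 0.4, center = c(1, 1), n_frames = 18)
  expect_error(unwrap_phase(sim$series, shrunk, 1), "empty wall mask")
})

test_that("decoding implements d = phi / (2 pi ke) in mm", {
  enc <- dense_encoding(ke = 0.25)
  fake <- list(ij = cbind(1:3, 1L), pos = cbind(1:3, 1),
               phi = cbind(c(0, pi, 2.2 * pi), c(0, 0, 0)))
  d <- decode_displacement(fake, enc)$d
  expect_equal(unname(d[, 1]), c(0, 2.0, 4.4), tolerance = 1e-12)
  expect_equal(unname(d[, 2]), c(0, 0, 0))
  expect_error(dense_encoding(ke = 0), "ke")
})

test_that("noise-free decode reproduces the analytic displacement below 1e-9 mm despite wrapping", {
  kin <- annulus_kinematics()   # excursion ~1.07 pi: spatial + temporal unwrap needed
  sim <- render_dense_series(kin, noise_sd = 0, seed = 1)
  back <- decode_series(sim$series, sim$contours)
  worst <- 0
  for (t in seq_len(kin$n_frames)) {
    e <- back$frames[[t]]
    Xref <- e$pos - e$d
    worst <- max(worst, max(abs(sim$truth$displacement_field(Xref, t) - e$d)))
  }
  expect_lt(worst, 1e-9)
})

test_that("tracking a uniform translation or zero field is exact and anchors u_1 = 0", {
  ij <- as.matrix(expand.grid(row = 1:6, col = 1:6))
  n <- nrow(ij)
  mk <- function(dvec) make_back_frame(ij, matrix(dvec, n, 2, byrow = TRUE))
  frames <- list(mk(c(0, 0)), mk(c(1.5, -0.5)), mk(c(1.5, -0.5)))
  traj <- track_forward(frames)
  expect_equal(max(abs(traj$U[, , 1])), 0)
  expect_equal(traj$U[, 1, 2], rep(1.5, n))
  expect_equal(traj$U[, 2, 3], rep(-0.5, n))
  traj0 <- track_forward(list(mk(c(0, 0)), mk(c(0, 0))))
  expect_equal(max(abs(traj0$U)), 0)
  expect_error(track_forward(list(mk(c(0, 0)), make_back_frame(ij[1:2, ], matrix(0, 2, 2)))),
               "frame 2")
})

test_that("inverse-distance interpolation is exact for symmetric neighbors and lattice hits on affine fields", {
  A <- matrix(c(0.05, 0.02, -0.01, 0.04), 2, 2)
  cc <- c(0.3, -0.2)
  affine_d <- function(X) t(A %*% t(X)) + matrix(cc, nrow(X), 2, byrow = TRUE)

  # equilateral neighbor triangle around the query: IDW mean = value at centroid = value at query
  query <- c(2, 3)
  org <- t(vapply(c(0, 2 * pi / 3, 4 * pi / 3),
                  function(a) query + 1.4 * c(cos(a), sin(a)), numeric(2)))
  d2 <- affine_d(org)
  f1 <- list(ij = cbind(1:3, 1L), pos = rbind(query, c(50, 50), c(-50, 50)),
             d = matrix(0, 3, 2))
  f2 <- list(ij = cbind(1:3, 1L), pos = org + d2, d = d2)
  traj <- track_forward(list(f1, f2))
  expect_equal(traj$U[1, , 2], unname(affine_d(rbind(query))[1, ]), tolerance = 1e-6)

  # back-projected origins coinciding with the reference lattice: exact-hit rule
  ij <- as.matrix(expand.grid(row = 1:5, col = 1:5))
  X <- cbind((ij[, 2] - 0.5), (ij[, 1] - 0.5))
  d <- affine_d(X)
  frames <- list(make_back_frame(ij, d * 0),
                 list(ij = ij, pos = X + d, d = d))
  traj <- track_forward(frames)
  expect_equal(max(abs(traj$U[, , 2] - d)), 0, tolerance = 1e-12)
})

test_that("tracked trajectories of a noise-free annulus stay within 0.1 voxel of the analytic map", {
  kin <- annulus_kinematics(stretch_amplitude = 0.1, heterogeneity = 0)
  sim <- render_dense_series(kin, noise_sd = 0, seed = 1)
  traj <- track_forward(decode_series(sim$series, sim$contours))
  worst <- 0
  for (t in seq_len(kin$n_frames)) {
    Xt <- tracked_positions(traj, t)
    worst <- max(worst, max(abs(Xt - deform_points(kin, traj$X1, t))))
  }
  expect_lt(worst / sim$series$encoding$voxel_size, 0.1)
})
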