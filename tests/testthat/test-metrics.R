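# Summary analytics: systole selection, NCS, heterogeneity, angles, geometry.

test_that("IAA/DTA systole is the argmax of mean strain with earliest-frame tie-breaking", {
  bump <- function(peak, nt = 18) exp(-0.5 * ((1:nt - peak) / 2)^2)
  map <- make_map(matrix(rep(0.1 * bump(8), each = 16), 16))
  expect_equal(select_systole(map, "IAA"), 8L)
  expect_equal(select_systole(map, "DTA"), 8L)
  twin <- 0.1 * pmax(bump(7), bump(9))   # equal maxima at frames 7 and 9
  map2 <- make_map(matrix(rep(twin, each = 16), 16))
  expect_equal(select_systole(map2, "IAA"), 7L)
  expect_error(select_systole(make_map(matrix(0, 16, 18)), "IAA"), "zero")
})

test_that("DAA systole averages the six earliest post-onset sector peaks with half-up rounding", {
  bump <- function(peak, nt = 18) exp(-0.5 * ((1:nt - peak) / 2)^2)
  peaks <- c(7, 7, 8, 8, 8, 9, rep(12, 10))   # first six -> mean 7.833 -> 8
  strain <- 0.1 * t(vapply(peaks, bump, numeric(18)))
  expect_equal(select_systole(make_map(strain), "DAA"), 8L)
  peaks2 <- c(7, 8, 8, 9, 9, 9, rep(13, 10))  # mean 8.333 -> 8
  strain2 <- 0.1 * t(vapply(peaks2, bump, numeric(18)))
  expect_equal(select_systole(make_map(strain2), "DAA"), 8L)
  peaks3 <- c(8, 8, 9, 9, 9, 9, rep(13, 10))  # mean 8.667 -> 9
  strain3 <- 0.1 * t(vapply(peaks3, bump, numeric(18)))
  expect_equal(select_systole(make_map(strain3), "DAA"), 9L)
})

test_that("select_systole recovers the generator's peak frame exactly on noise-free data", {
  sim <- render_dense_series(annulus_kinematics(heterogeneity = 0.3,
                                                peak_angle = pi / 2),
                             noise_sd = 0, seed = 4)
  for (loc in c("IAA", "DTA", "DAA")) {
    fit <- dense_strain(sim$series, sim$contours, location = loc, temporal_window = 1)
    expect_equal(fit$summary$systole_frame, sim$truth$systole_frame_true)
  }
})

test_that("NCS normalizes to mean 1 and reproduces hand arithmetic", {
  s <- matrix(0.10, 16, 18); s[, 8] <- 0.10
  map <- make_map(s)
  r <- compute_ncs(map, 8)
  expect_equal(unname(r$ncs), rep(1, 16))
  expect_equal(r$max_ncs, 1)

  s2 <- matrix(0.10, 16, 18); s2[7, ] <- 0.25
  r2 <- compute_ncs(make_map(s2), 8)
  expect_equal(r2$ncs[7], 0.25 / 0.109375, tolerance = 1e-12)  # = 2.2857
  expect_equal(r2$ncs[7], 2.2857, tolerance = 1e-3)
  expect_equal(r2$peak_sector, 7L)
  expect_equal(mean(r2$ncs), 1, tolerance = 1e-12)

  expect_error(compute_ncs(make_map(matrix(1e-9, 16, 18)), 8), "too small")
})

test_that("maximum NCS searches all frames, not only local systole", {
  s <- matrix(0.10, 16, 18)
  s[3, 12] <- 0.30    # late peak after systole
  s[, 8] <- 0.12      # systole frame has the largest mean
  map <- make_map(s)
  sys <- select_systole(map, "DTA")
  expect_equal(sys, 8L)
  r <- compute_ncs(map, sys)
  expect_equal(r$max_ncs, 0.30 / 0.12, tolerance = 1e-12)
  expect_equal(r$max_ncs_sector, 3L)
  expect_equal(r$max_ncs_frame, 12L)
})

test_that("heterogeneity index is the sample SD over mean, scale-invariant, zero when homogeneous", {
  s <- matrix(0.1, 16, 18)
  expect_equal(heterogeneity_index(make_map(s), 8), 0)
  s2 <- s; s2[, 8] <- rep(c(0.1, 0.2), 8)
  expect_equal(heterogeneity_index(make_map(s2), 8),
               sqrt(16 * 0.05^2 / 15) / 0.15, tolerance = 1e-12)
  expect_equal(heterogeneity_index(make_map(s2), 8), 0.3443, tolerance = 1e-3)
  for (c_scale in c(0.1, 10)) {
    expect_equal(heterogeneity_index(make_map(s2 * c_scale), 8),
                 heterogeneity_index(make_map(s2), 8), tolerance = 1e-12)
  }
})

test_that("displacement angle uses the left-lateral zero, anterior-positive convention", {
  mk <- function(ux, uy) {   # image y is posterior, so anterior is -y
    U <- array(0, c(4, 2, 8)); U[, 1, 8] <- ux; U[, 2, 8] <- uy
    make_traj(matrix(0, 4, 2), U)
  }
  expect_equal(mean_displacement_angle(mk(1, 0), 8)$angle_deg, 0)
  expect_equal(mean_displacement_angle(mk(0, -1), 8)$angle_deg, 90)
  expect_equal(mean_displacement_angle(mk(0.5, -0.866), 8)$angle_deg, 60, tolerance = 1e-3)
  expect_equal(mean_displacement_angle(mk(-1, 0), 8)$angle_deg, 180)
  z <- mean_displacement_angle(mk(0, 0), 8)
  expect_false(z$defined)
  expect_true(is.na(z$angle_deg))
  expect_equal(z$magnitude_mm, 0)
})

test_that("DAA alignment chooses the rotation restoring a shifted map, with r = 0 on ties", {
  ref <- 1 + 0.3 * cos(2 * pi * (0:15) / 16)
  shifted <- ref[c(16, 1:15)]               # reference shifted by +1 sector
  al <- align_daa_map(shifted, ref)
  expect_equal(al$rotation, -1L)
  expect_equal(al$aligned, ref, tolerance = 1e-12)
  expect_equal(align_daa_map(ref, ref)$rotation, 0L)
  flat <- align_daa_map(rep(1, 16), ref)
  expect_equal(flat$rotation, 0L)
  expect_true(flat$degenerate)
})

test_that("DAA alignment finds the true shift under 10% noise in at least 95 of 100 seeds", {
  ref <- 1 + 0.3 * cos(2 * pi * (0:15) / 16)
  set.seed(123)
  correct <- 0
  for (i in 1:100) {
    noisy <- ref[c(16, 1:15)] + rnorm(16, 0, 0.03)   # SD = 10% of amplitude
    if (align_daa_map(noisy, ref)$rotation == -1L) correct <- correct + 1
  }
  expect_gte(correct, 95)
})

test_that("diastolic geometry returns the mid-wall diameter and BSA-relative size", {
  expect_equal(diastolic_geometry(circle_contours(r_in = 7, r_out = 9))$diameter_cm,
               1.6, tolerance = 1e-3)
  g <- diastolic_geometry(circle_contours(r_in = 7, r_out = 9), bsa = 1.8)
  expect_equal(g$relative_size, 1.6 / 1.8, tolerance = 1e-3)
  expect_equal(g$relative_size, 0.889, tolerance = 1e-3)
  # elliptical mid-wall with extents 20 x 24 mm -> 2.2 cm
  th <- 2 * pi * (0:95) / 96
  ell <- function(s) cbind(30 + s * 10 * cos(th), 30 + s * 12 * sin(th))
  ct <- wall_contours(rep(list(ell(0.9)), 3), rep(list(ell(1.1)), 3))
  expect_equal(diastolic_geometry(ct)$diameter_cm, 2.2, tolerance = 5e-3)
  miss <- diastolic_geometry(circle_contours())
  expect_true(miss$bsa_missing)
  expect_true(is.na(miss$relative_size))
  expect_error(diastolic_geometry(circle_contours(), bsa = -1), "bsa")
})

test_that("NCS, peak location and heterogeneity are invariant under strain rescaling on random maps", {
  set.seed(2025)
  for (i in 1:25) {
    s <- matrix(stats::rlnorm(16 * 18, log(0.08), 0.4), 16, 18)
    map <- make_map(s)
    sys <- select_systole(map, "DTA")
    base <- compute_ncs(map, sys)
    for (c_scale in c(0.1, 10)) {
      sc <- compute_ncs(make_map(s * c_scale), sys)
      expect_equal(sc$ncs, base$ncs, tolerance = 1e-10)
      expect_equal(sc$max_ncs, base$max_ncs, tolerance = 1e-10)
    }
    expect_equal(mean(base$ncs), 1, tolerance = 1e-12)
  }
})
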