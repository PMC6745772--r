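#' Analytic kinematics of a deforming annular wall
#'
#' Defines the motion model used by the synthetic DENSE generator: an annulus
#' (inner/outer radius at the reference configuration) subjected to a bulk
#' translation plus an angle-dependent radial stretch,
#' \deqn{x(X, t) = c + b(t) + \lambda(\Theta, t)\,(X - c),}
#' with
#' \deqn{\lambda(\Theta, t) = 1 + A\,p(t)\,\frac{1 + h\cos(\Theta - \Theta_{peak})}{1 + h},}
#' where \eqn{\Theta} is the anatomical polar angle of the reference point
#' \eqn{X} about the center \eqn{c}, \eqn{p(t) \in [0,1]} is a smooth systolic
#' profile with its maximum (exactly 1) at `t_peak`, and
#' \eqn{b(t) = b_{max} p(t)}. With heterogeneity `h = 0` the wall stretches
#' uniformly; `0 < h < 1` concentrates stretch around `peak_angle` while
#' keeping \eqn{\lambda > 1} everywhere when `stretch_amplitude > 0`.
#'
#' Angles follow the package convention: 0 = left-lateral (+x image axis),
#' increasing counterclockwise in the axial anatomical view (anterior up).
#'
#' @param center reference center of the annulus, mm (image coordinates).
#' @param inner_radius,outer_radius luminal / adventitial radii at the
#'   reference configuration, mm; `0 < inner_radius < outer_radius`.
#' @param stretch_amplitude peak mean circumferential stretch increment
#'   \eqn{A} (dimensionless); 0.10 gives a peak mean stretch ratio of 1.10.
#' @param heterogeneity circumferential heterogeneity \eqn{h \in [0, 1)}.
#' @param peak_angle anatomical angle (radians) at which stretch peaks.
#' @param translation peak bulk translation \eqn{b_{max}}, mm (image xy).
#' @param n_frames number of cine frames (>= 2).
#' @param t_peak frame index of peak deformation.
#' @param frame_interval frame spacing, ms (metadata only).
#' @param profile optional temporal profile `function(t)` on frame indices,
#'   values in \[0, 1\] with `profile(t_peak) == 1`. Default: raised cosine
#'   rising over frames `1..t_peak` and decaying back to 0 at `n_frames`.
#' @return An object of class `annulus_kinematics`.
#' @examples
#' kin <- annulus_kinematics(stretch_amplitude = 0.1, heterogeneity = 0)
#' deform_points(kin, kin$center + c(10, 0), t = kin$t_peak)
#' @export
annulus_kinematics <- function(center = c(24, 24),
                               inner_radius = 8,
                               outer_radius = 12,
                               stretch_amplitude = 0.10,
                               heterogeneity = 0,
                               peak_angle = 0,
                               translation = c(1.0, -0.5),
                               n_frames = 18L,
                               t_peak = 8L,
                               frame_interval = 32,
                               profile = NULL) {
  if (!is.numeric(center) || length(center) != 2L)
    .stopf("invalid 'center': must be a numeric 2-vector")
  if (!.is_number(inner_radius) || inner_radius <= 0)
    .stopf("invalid 'inner_radius': must be > 0")
  if (!.is_number(outer_radius) || outer_radius <= inner_radius)
    .stopf("invalid 'outer_radius': must exceed 'inner_radius'")
  if (!.is_number(stretch_amplitude) || stretch_amplitude < 0)
    .stopf("invalid 'stretch_amplitude': must be >= 0")
  if (!.is_number(heterogeneity) || heterogeneity < 0 || heterogeneity >= 1)
    .stopf("invalid 'heterogeneity': must be in [0, 1)")
  if (!.is_number(peak_angle))
    .stopf("invalid 'peak_angle': must be a finite number")
  if (!is.numeric(translation) || length(translation) != 2L)
    .stopf("invalid 'translation': must be a numeric 2-vector")
  n_frames <- as.integer(n_frames)
  t_peak <- as.integer(t_peak)
  if (is.na(n_frames) || n_frames < 2L)
    .stopf("invalid 'n_frames': need at least 2 frames")
  if (is.na(t_peak) || t_peak < 1L || t_peak > n_frames)
    .stopf("invalid 't_peak': must lie in [1, n_frames]")

  if (is.null(profile)) {
    profile <- function(t) {
      rise <- if (t_peak > 1L) 0.5 * (1 - cos(pi * (t - 1) / (t_peak - 1))) else 1
      fall <- if (t_peak < n_frames) 0.5 * (1 + cos(pi * (t - t_peak) / (n_frames - t_peak))) else 1
      ifelse(t <= t_peak, rise, fall)
    }
  }
  prof <- profile(seq_len(n_frames))
  if (length(prof) != n_frames || any(!is.finite(prof)))
    .stopf("invalid 'profile': must return one finite value per frame")
  if (any(prof < -1e-12) || any(prof > 1 + 1e-12))
    .stopf("invalid 'profile': values must lie in [0, 1]")
  if (abs(prof[t_peak] - 1) > 1e-12 || max(prof) > prof[t_peak] + 1e-12)
    .stopf("invalid 'profile': maximum must be exactly 1 at t_peak")
  prof <- pmin(pmax(prof, 0), 1)

  structure(
    list(center = as.numeric(center), inner_radius = inner_radius,
         outer_radius = outer_radius, stretch_amplitude = stretch_amplitude,
         heterogeneity = heterogeneity, peak_angle = peak_angle,
         translation = as.numeric(translation), n_frames = n_frames,
         t_peak = t_peak, frame_interval = frame_interval,
         profile = profile, profile_values = prof),
    class = "annulus_kinematics")
}

#' @export
print.annulus_kinematics <- function(x, ...) {
  cat("Annulus kinematics:\n")
  cat(sprintf("  radii %.2f / %.2f mm about (%.1f, %.1f) mm\n",
              x$inner_radius, x$outer_radius, x$center[1], x$center[2]))
  cat(sprintf("  stretch amplitude %.3f, heterogeneity %.2f (peak angle %.2f rad)\n",
              x$stretch_amplitude, x$heterogeneity, x$peak_angle))
  cat(sprintf("  translation (%.2f, %.2f) mm, %d frames, peak at frame %d\n",
              x$translation[1], x$translation[2], x$n_frames, x$t_peak))
  invisible(x)
}

# stretch ratio lambda(theta, t); theta = anatomical angle, t = frame index
.lambda <- function(kin, theta, t) {
  p <- kin$profile_values[t]
  1 + kin$stretch_amplitude * p *
    (1 + kin$heterogeneity * cos(theta - kin$peak_angle)) / (1 + kin$heterogeneity)
}

#' Map reference points through the analytic deformation
#'
#' @param kin an [annulus_kinematics()] object.
#' @param points n x 2 matrix (or 2-vector) of reference positions, mm.
#' @param t frame index.
#' @return n x 2 matrix of deformed positions, mm.
#' @export
deform_points <- function(kin, points, t) {
  stopifnot(inherits(kin, "annulus_kinematics"))
  t <- as.integer(t)
  if (t < 1L || t > kin$n_frames) .stopf("frame %d outside [1, %d]", t, kin$n_frames)
  X <- .as_points(points)
  q <- sweep(X, 2L, kin$center)
  theta <- .anat_angle(q[, 1L], q[, 2L])
  lam <- .lambda(kin, theta, t)
  b <- kin$translation * kin$profile_values[t]
  cbind(kin$center[1L] + b[1L] + lam * q[, 1L],
        kin$center[2L] + b[2L] + lam * q[, 2L])
}

# inverse map: observed position at frame t -> reference position.
# The deformation scales along rays from the (translated) center, so the
# anatomical angle is preserved and the inverse is closed-form.
.invert_points <- function(kin, points, t) {
  p <- .as_points(points)
  b <- kin$translation * kin$profile_values[t]
  q <- cbind(p[, 1L] - kin$center[1L] - b[1L], p[, 2L] - kin$center[2L] - b[2L])
  theta <- .anat_angle(q[, 1L], q[, 2L])
  lam <- .lambda(kin, theta, t)
  cbind(kin$center[1L] + q[, 1L] / lam, kin$center[2L] + q[, 2L] / lam)
}

#' Ground-truth sector strain by numerical differentiation
#'
#' Independent oracle for the strain pipeline: evaluates the deformation
#' gradient of the analytic annulus motion by central finite differences on a
#' fine step at the mid-wall point of each circumferential sector, forms the
#' Green-Lagrange tensor \eqn{E = (F^T F - I)/2}, and rotates it to the local
#' radial-circumferential axes. For a homogeneous stretch \eqn{\lambda} this
#' equals the closed form \eqn{E_{\theta\theta} = (\lambda^2 - 1)/2}.
#'
#' @param kin an [annulus_kinematics()] object.
#' @param n_sectors number of circumferential sectors (default 16).
#' @param frames frame indices to evaluate (default all).
#' @param step finite-difference step, mm (<= 0.01).
#' @param avi_angle optional aorto-vertebral interface angle; when supplied,
#'   rows are renumbered so sector 1 is the first sector counterclockwise of
#'   it (same rule as [assemble_sector_map()]). Default keeps internal
#'   numbering (bins anchored at anatomical angle 0).
#' @return `n_sectors` x `length(frames)` matrix of circumferential Green
#'   strain values.
#' @export
true_sector_strain <- function(kin, n_sectors = 16L,
                               frames = seq_len(kin$n_frames),
                               step = 0.005, avi_angle = NULL) {
  stopifnot(inherits(kin, "annulus_kinematics"))
  if (!.is_number(step) || step <= 0 || step > 0.01)
    .stopf("invalid 'step': must be in (0, 0.01] mm")
  n_sectors <- as.integer(n_sectors)
  w <- .sector_width(n_sectors)
  theta_s <- (seq_len(n_sectors) - 0.5) * w
  r_mid <- (kin$inner_radius + kin$outer_radius) / 2
  Xs <- sweep(r_mid * .anat_unit(theta_s), 2L, -kin$center)
  tang <- .anat_tangent(theta_s)

  out <- matrix(NA_real_, n_sectors, length(frames))
  h1 <- cbind(rep(step, n_sectors), 0)
  h2 <- cbind(0, rep(step, n_sectors))
  for (k in seq_along(frames)) {
    t <- frames[k]
    xp1 <- deform_points(kin, Xs + h1, t)
    xm1 <- deform_points(kin, Xs - h1, t)
    xp2 <- deform_points(kin, Xs + h2, t)
    xm2 <- deform_points(kin, Xs - h2, t)
    F11 <- (xp1[, 1L] - xm1[, 1L]) / (2 * step)
    F21 <- (xp1[, 2L] - xm1[, 2L]) / (2 * step)
    F12 <- (xp2[, 1L] - xm2[, 1L]) / (2 * step)
    F22 <- (xp2[, 2L] - xm2[, 2L]) / (2 * step)
    E11 <- (F11^2 + F21^2 - 1) / 2
    E22 <- (F12^2 + F22^2 - 1) / 2
    E12 <- (F11 * F12 + F21 * F22) / 2
    out[, k] <- tang[, 1L]^2 * E11 + 2 * tang[, 1L] * tang[, 2L] * E12 +
      tang[, 2L]^2 * E22
  }
  dimnames(out) <- list(sector = seq_len(n_sectors), frame = frames)
  if (!is.null(avi_angle)) {
    lab <- .avi_label(seq_len(n_sectors), avi_angle, n_sectors)
    out2 <- out
    out2[lab, ] <- out
    rownames(out2) <- seq_len(n_sectors)
    out <- out2
  }
  out
}
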