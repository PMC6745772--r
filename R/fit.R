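#' Fit the regional aortic strain model to a DENSE acquisition
#'
#' Runs the full post-processing pipeline on one cine DENSE cross-section:
#' masked phase unwrapping, displacement decoding (\eqn{d = \varphi / 2\pi
#' k_e}), spatial smoothing of the displacement field, Lagrangian forward
#' tracking from the three closest back-projected displacement vectors,
#' temporal smoothing of the tracked positions, bilinear quadrilateral
#' finite-element Green strain over 16 circumferential sectors rotated to
#' radial-circumferential axes and time-smoothed with a fifth-order
#' polynomial, and the summary indices: local-systole frame, normalized
#' circumferential strain (NCS), heterogeneity index, mean displacement
#' angle, diastolic diameter and relative aortic size.
#'
#' @param series a [dense_series()] object (or [read_dense_series()] result).
#' @param contours a [wall_contours()] object (or [read_contours()] result).
#' @param location aortic location: `"IAA"`, `"DTA"` or `"DAA"`. Sets the
#'   default spatial smoothing radius (2 voxel-spaces at the IAA, else 1)
#'   and the local-systole rule.
#' @param avi_angle anatomical angle of the aorto-vertebral interface about
#'   the wall centroid, radians (0 = left-lateral, counterclockwise
#'   positive); sector 1 is the first sector counterclockwise from it.
#' @param bsa body surface area in m^2, for relative aortic size (optional).
#' @param spatial_radius displacement smoothing radius in voxel-spaces (1 or
#'   2); default by location.
#' @param temporal_window odd moving-average window (frames) for position
#'   smoothing; 1 disables it.
#' @param strain_smooth apply the fifth-order polynomial time-smoothing of
#'   the sector strain series (default TRUE).
#' @param systole_threshold onset fraction for the DAA local-systole rule.
#' @param daa_reference optional length-16 reference NCS map; when given and
#'   `location = "DAA"`, the fitted NCS map is aligned to it by at most one
#'   sector rotation ([align_daa_map()]).
#' @return An object of class `dense_strain`: list with `map`
#'   (`sector_strain_map`), `summary` (`strain_summary`), `trajectories`
#'   (`trajectory_field`), `elements`, `alignment` (or `NULL`) and `config`.
#'   Methods: `print`, `summary`, `coef` (NCS or raw sector strain), `plot`.
#' @examples
#' sim <- render_dense_series(annulus_kinematics(heterogeneity = 0.3,
#'                                               peak_angle = pi / 2),
#'                            noise_sd = 0.05, seed = 7)
#' fit <- dense_strain(sim$series, sim$contours, location = "DTA")
#' fit
#' coef(fit)
#' @export
dense_strain <- function(series, contours,
                         location = c("DTA", "IAA", "DAA"),
                         avi_angle = 0, bsa = NULL,
                         spatial_radius = NULL,
                         temporal_window = 3L,
                         strain_smooth = TRUE,
                         systole_threshold = 0.1,
                         daa_reference = NULL) {
  stopifnot(inherits(series, "dense_series"), inherits(contours, "wall_contours"))
  location <- match.arg(location)
  if (is.null(spatial_radius)) spatial_radius <- if (location == "IAA") 2L else 1L

  back <- decode_series(series, contours)
  back <- spatial_smooth(back, radius = spatial_radius)
  traj <- track_forward(back)
  traj <- temporal_smooth_positions(traj, window = temporal_window)
  elements <- build_sector_elements(traj, contours)
  map <- assemble_sector_map(elements, avi_angle = avi_angle,
                             location = location, strain_smooth = strain_smooth)
  systole <- select_systole(map, location, threshold = systole_threshold)
  ncs <- compute_ncs(map, systole)
  het <- heterogeneity_index(map, systole)
  disp <- mean_displacement_angle(traj, systole)
  geo <- diastolic_geometry(contours, bsa)

  alignment <- NULL
  if (location == "DAA" && !is.null(daa_reference)) {
    alignment <- align_daa_map(ncs$ncs, daa_reference)
  }

  summary <- structure(list(
    systole_frame = systole,
    mean_strain_systole = ncs$mean_strain_systole,
    ncs = ncs$ncs, max_ncs = ncs$max_ncs,
    max_ncs_sector = ncs$max_ncs_sector, max_ncs_frame = ncs$max_ncs_frame,
    peak_sector = ncs$peak_sector,
    peak_sector_offset_from_avi =
      .sector_offset_from_avi(ncs$peak_sector, map$n_sectors),
    het_index = het,
    mean_disp_angle_deg = disp$angle_deg,
    disp_magnitude_mm = disp$magnitude_mm,
    diameter_cm = geo$diameter_cm, relative_size = geo$relative_size,
    n_valid_sectors = map$n_valid, location = location,
    conventions = list(
      angle_zero = "left-lateral (+x image axis)",
      angle_positive = "counterclockwise in the axial anatomical view (anterior)",
      reference_frame = 1L,
      strain = "Green-Lagrange, referential gradient (d u / d X)",
      sector_numbering = "sector 1 first counterclockwise from the AVI",
      sd = "sample (n - 1)",
      temporal_position_smoothing = "centered moving average, truncated edges")),
    class = "strain_summary")

  structure(list(map = map, summary = summary, trajectories = traj,
                 elements = elements, alignment = alignment,
                 config = list(location = location, avi_angle = avi_angle,
                               bsa = bsa, spatial_radius = spatial_radius,
                               temporal_window = as.integer(temporal_window),
                               strain_smooth = strain_smooth,
                               systole_threshold = systole_threshold),
                 call = match.call()),
            class = "dense_strain")
}

#' @export
print.dense_strain <- function(x, ...) {
  sm <- x$summary
  cat(sprintf("Aortic DENSE strain fit (%s), %d/%d valid sectors\n",
              sm$location, sm$n_valid_sectors, x$map$n_sectors))
  cat(sprintf("  local systole at frame %d; mean circumferential strain %.4f\n",
              sm$systole_frame, sm$mean_strain_systole))
  cat(sprintf("  max NCS %.3f (sector %d, frame %d); heterogeneity index %.3f\n",
              sm$max_ncs, sm$max_ncs_sector, sm$max_ncs_frame, sm$het_index))
  cat(sprintf("  mean displacement %.2f mm at %s deg; diameter %.2f cm\n",
              sm$disp_magnitude_mm,
              ifelse(is.na(sm$mean_disp_angle_deg), "NA",
                     sprintf("%.1f", sm$mean_disp_angle_deg)),
              sm$diameter_cm))
  invisible(x)
}

#' @export
summary.dense_strain <- function(object, ...) {
  sm <- object$summary
  sm$sector_table <- data.frame(
    sector = seq_len(object$map$n_sectors),
    strain_systole = object$map$strain[, sm$systole_frame],
    ncs = sm$ncs,
    valid = object$map$valid)
  class(sm) <- c("summary.dense_strain", "strain_summary")
  sm
}

#' @export
print.summary.dense_strain <- function(x, ...) {
  cat(sprintf("Aortic DENSE strain summary (%s)\n", x$location))
  cat(sprintf("  systole frame %d | mean strain %.4f | max NCS %.3f | het index %.3f\n",
              x$systole_frame, x$mean_strain_systole, x$max_ncs, x$het_index))
  if (!is.na(x$relative_size))
    cat(sprintf("  diameter %.2f cm | relative size %.3f cm/m^2\n",
                x$diameter_cm, x$relative_size))
  else
    cat(sprintf("  diameter %.2f cm\n", x$diameter_cm))
  cat("\nPer-sector values at local systole (AVI numbering):\n")
  print(format(x$sector_table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
coef.dense_strain <- function(object, type = c("ncs", "strain"), ...) {
  type <- match.arg(type)
  v <- if (type == "ncs") object$summary$ncs
       else object$map$strain[, object$summary$systole_frame]
  stats::setNames(v, paste0("sector", seq_along(v)))
}

#' Plot a fitted sector strain map
#'
#' Left panel: per-sector circumferential strain time-courses with the
#' local-systole frame marked. Right panel: NCS around the circumference at
#' local systole (sector 1 at the aorto-vertebral interface, proceeding
#' counterclockwise).
#'
#' @param x a `dense_strain` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.dense_strain <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  nt <- ncol(x$map$strain)
  graphics::matplot(seq_len(nt), t(x$map$strain), type = "l", lty = 1,
                    col = grDevices::hcl.colors(x$map$n_sectors, "viridis"),
                    xlab = "frame", ylab = "circumferential Green strain",
                    main = "sector strain time-courses", ...)
  graphics::abline(v = x$summary$systole_frame, lty = 2, col = "grey40")
  ncs <- x$summary$ncs
  graphics::plot(seq_along(ncs), ncs, type = "b", pch = 16,
                 xlab = "sector (1 = first CCW from AVI)", ylab = "NCS",
                 main = sprintf("NCS at systole (frame %d)", x$summary$systole_frame))
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}
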