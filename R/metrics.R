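#' Select the local-systole frame
#'
#' At the infrarenal abdominal aorta (IAA) and mid-descending thoracic aorta
#' (DTA), local systole is the frame with the largest mean circumferential
#' strain over the cross-section (earliest frame on ties). At the distal
#' aortic arch (DAA), where some sectors peak in local diastole, it is the
#' mean (rounded half-up) of the peak frames of the first six sectors that
#' peak after the beginning of local systole, operationalized as the first
#' frame at which the mean strain exceeds `threshold` times its eventual
#' maximum.
#'
#' @param map a `sector_strain_map` from [assemble_sector_map()].
#' @param location `"IAA"`, `"DTA"` or `"DAA"`; defaults to the map's label.
#' @param threshold DAA local-systole onset fraction (default 0.1).
#' @return Frame index of local systole.
#' @export
select_systole <- function(map, location = map$location, threshold = 0.1) {
  stopifnot(inherits(map, "sector_strain_map"))
  location <- match.arg(location, c("IAA", "DTA", "DAA"))
  mean_series <- colMeans(map$strain[map$valid, , drop = FALSE])
  if (all(abs(mean_series) < 1e-12))
    .stopf("no systole: mean strain series is identically zero")
  if (location != "DAA") return(which.max(mean_series))

  mmax <- max(mean_series)
  start <- which(mean_series > threshold * mmax)[1L]
  if (is.na(start)) .stopf("no systole: mean strain never exceeds the onset threshold")
  sectors <- which(map$valid)
  peak_frame <- vapply(sectors, function(s) {
    sub <- map$strain[s, start:ncol(map$strain)]
    start + which.max(sub) - 1L
  }, integer(1L))
  first6 <- sectors[order(peak_frame)][seq_len(min(6L, length(sectors)))]
  m <- mean(peak_frame[match(first6, sectors)])
  as.integer(floor(m + 0.5))                      # round half-up
}

#' Normalized circumferential strain (NCS)
#'
#' Each sector's circumferential strain at local systole divided by the mean
#' circumferential strain over valid sectors at that frame, so that NCS
#' averages exactly 1. `max_ncs` is the highest value of sector strain
#' divided by the systolic mean over all sectors *and all frames* (maximum
#' NCS can occur outside local systole).
#'
#' @param map a `sector_strain_map`.
#' @param systole_frame frame index from [select_systole()].
#' @return list with `ncs` (length-16, `NA` for invalid sectors),
#'   `mean_strain_systole`, `max_ncs`, `max_ncs_sector`, `max_ncs_frame`,
#'   `peak_sector` (argmax of NCS at systole).
#' @export
compute_ncs <- function(map, systole_frame) {
  stopifnot(inherits(map, "sector_strain_map"))
  s_sys <- map$strain[, systole_frame]
  mean_sys <- mean(s_sys[map$valid])
  if (!is.finite(mean_sys) || mean_sys <= 1e-6)
    .stopf("strain too small to normalize: mean systolic strain = %g (rigid motion?)",
           mean_sys)
  ncs <- s_sys / mean_sys
  rel <- map$strain / mean_sys
  rel[!map$valid, ] <- NA_real_
  peak_idx <- arrayInd(which.max(rel), dim(rel))
  list(ncs = ncs, mean_strain_systole = mean_sys,
       max_ncs = max(rel, na.rm = TRUE),
       max_ncs_sector = peak_idx[1L], max_ncs_frame = peak_idx[2L],
       peak_sector = which.max(ifelse(map$valid, ncs, -Inf)))
}

#' Strain heterogeneity index
#'
#' Sample standard deviation (n - 1 denominator) of the 16 sector
#' circumferential strains at local systole divided by their mean; 0 for a
#' homogeneous deformation and invariant under scaling of the strain.
#'
#' @inheritParams compute_ncs
#' @return Dimensionless heterogeneity index.
#' @export
heterogeneity_index <- function(map, systole_frame) {
  stopifnot(inherits(map, "sector_strain_map"))
  s_sys <- map$strain[map$valid, systole_frame]
  if (length(s_sys) < 2L) .stopf("heterogeneity index needs at least 2 valid sectors")
  m <- mean(s_sys)
  if (!is.finite(m) || m <= 1e-6)
    .stopf("strain too small to normalize: mean systolic strain = %g", m)
  stats::sd(s_sys) / m
}

#' Mean displacement angle at systole
#'
#' Mean forward displacement over all wall voxels at the systolic frame,
#' expressed as an angle with 0 pointing left-lateral and positive angles
#' anterior (counterclockwise in the axial view), in degrees in (-180, 180].
#'
#' @param traj a `trajectory_field`.
#' @param systole_frame frame index.
#' @return list with `angle_deg` (`NA` when the mean displacement is zero),
#'   `magnitude_mm`, and `defined`.
#' @export
mean_displacement_angle <- function(traj, systole_frame) {
  stopifnot(inherits(traj, "trajectory_field"))
  mu <- colMeans(traj$U[, , systole_frame, drop = FALSE][, , 1L])
  mag <- sqrt(sum(mu^2))
  if (mag < 1e-12)
    return(list(angle_deg = NA_real_, magnitude_mm = 0, defined = FALSE))
  ang <- .anat_angle(mu[1L], mu[2L]) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  list(angle_deg = ang, magnitude_mm = mag, defined = TRUE)
}

#' Align a distal-arch sector map to a reference by +/- 1 sector
#'
#' Distal aortic arch (DAA) cross-sections are patient-specific obliques, so
#' each 16-sector map is allowed a rotation of one sector in either
#' direction to best align its strain extrema with a reference map. The
#' rotation maximizing the Pearson correlation with the reference is chosen;
#' ties prefer no rotation, then the smaller magnitude (-1 before +1).
#'
#' @param values length-16 sector values (e.g. NCS at local systole).
#' @param reference length-16 reference map.
#' @return list with `rotation` (-1, 0 or +1), `aligned` (rotated values
#'   such that `aligned[s] = values[s - rotation]`, circularly), and
#'   `degenerate` (TRUE when a constant map made the correlation undefined).
#' @export
align_daa_map <- function(values, reference) {
  if (length(values) != length(reference))
    .stopf("map and reference must have the same number of sectors")
  n <- length(values)
  rotate <- function(v, r) v[((seq_len(n) - 1L - r) %% n) + 1L]
  if (stats::sd(values) < 1e-15 || stats::sd(reference) < 1e-15)
    return(list(rotation = 0L, aligned = values, degenerate = TRUE))
  cand <- c(0L, -1L, 1L)
  cors <- vapply(cand, function(r) stats::cor(rotate(values, r), reference), numeric(1L))
  best <- cand[which.max(cors > max(cors) - 1e-12)]   # first candidate at max
  list(rotation = best, aligned = rotate(values, best), degenerate = FALSE)
}

#' Diastolic aortic diameter and relative aortic size
#'
#' The diameter is the average of the mid-wall contour's x- and y-extents at
#' the diastolic reference frame (frame 1), in cm; relative aortic size is
#' the diameter divided by body surface area.
#'
#' @param contours a [wall_contours()] object.
#' @param bsa body surface area, m^2 (optional).
#' @return list with `diameter_cm`, `relative_size` (`NA` with
#'   `bsa_missing = TRUE` when `bsa` is not supplied).
#' @export
diastolic_geometry <- function(contours, bsa = NULL) {
  stopifnot(inherits(contours, "wall_contours"))
  mw <- .midwall_contour(contours, 1L)
  ext_x <- diff(range(mw$points[, 1L]))
  ext_y <- diff(range(mw$points[, 2L]))
  diameter_cm <- mean(c(ext_x, ext_y)) / 10
  if (is.null(bsa))
    return(list(diameter_cm = diameter_cm, relative_size = NA_real_,
                bsa_missing = TRUE))
  if (!.is_number(bsa) || bsa <= 0) .stopf("invalid 'bsa': must be > 0 m^2")
  list(diameter_cm = diameter_cm, relative_size = diameter_cm / bsa,
       bsa_missing = FALSE)
}

# signed counterclockwise sector offset from the AVI (sector 1 -> 0),
# mapped to (-n/2, n/2]
.sector_offset_from_avi <- function(sector, n_sectors) {
  v <- (as.integer(sector) - 1L) %% n_sectors
  ifelse(v > n_sectors / 2, v - n_sectors, v)
}
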