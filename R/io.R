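# Readers/writers for the pipeline's external artifacts: NIfTI/TIFF image
# stacks, contour polygon files (JSON/CSV), and sector-table output.

.stack_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return("tiff")
  .stopf("unsupported image format: %s (use .nii, .nii.gz or .tif)", path)
}

.read_stack <- function(path) {
  if (!file.exists(path)) .stopf("unreadable file: %s", path)
  if (.stack_format(path) == "nifti") {
    arr <- as.array(RNifti::readNifti(path))
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      .stopf("package 'tiff' is required to read %s", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    arr <- simplify2array(frames)
  }
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (length(dim(arr)) != 3L)
    .stopf("%s: expected a 2-D multi-frame stack, got dims %s",
           path, paste(dim(arr), collapse = "x"))
  arr
}

.write_stack <- function(arr, path, voxel_size, frame_interval, scale01 = FALSE) {
  if (.stack_format(path) == "nifti") {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(voxel_size, voxel_size, frame_interval)
    RNifti::writeNifti(img, path)
    return(invisible(NULL))
  }
  if (!requireNamespace("tiff", quietly = TRUE))
    .stopf("package 'tiff' is required to write %s", path)
  frames <- lapply(seq_len(dim(arr)[3L]), function(t) arr[, , t])
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(NULL)
}

#' Write a DENSE series to disk
#'
#' NIfTI stacks (`.nii` / `.nii.gz`) store the data verbatim as 64-bit
#' floats. TIFF stacks are written as 32-bit samples scaled to `[0, 1]`:
#' phases as `(phi + pi) / (2 pi)` and magnitude divided by
#' `max(1, max(magnitude))`; the scaling and the encoding parameters are
#' recorded in a `params.json` sidecar next to the files so that
#' [read_dense_series()] can invert it.
#'
#' @param series a [dense_series()] object.
#' @param dir output directory (created if missing).
#' @param format `"nifti"` (default) or `"tiff"`.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dense_series <- function(series, dir, format = c("nifti", "tiff")) {
  stopifnot(inherits(series, "dense_series"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "nifti") ".nii.gz" else ".tif"
  paths <- c(magnitude = file.path(dir, paste0("mag", ext)),
             phase_x = file.path(dir, paste0("phx", ext)),
             phase_y = file.path(dir, paste0("phy", ext)))
  enc <- series$encoding
  mag_scale <- 1
  if (format == "nifti") {
    .write_stack(series$magnitude, paths["magnitude"], enc$voxel_size, enc$frame_interval)
    .write_stack(series$phase_x, paths["phase_x"], enc$voxel_size, enc$frame_interval)
    .write_stack(series$phase_y, paths["phase_y"], enc$voxel_size, enc$frame_interval)
  } else {
    mag_scale <- max(1, max(series$magnitude))
    .write_stack(pmax(series$magnitude, 0) / mag_scale, paths["magnitude"],
                 enc$voxel_size, enc$frame_interval)
    .write_stack((series$phase_x + pi) / (2 * pi), paths["phase_x"],
                 enc$voxel_size, enc$frame_interval)
    .write_stack((series$phase_y + pi) / (2 * pi), paths["phase_y"],
                 enc$voxel_size, enc$frame_interval)
  }
  params <- list(ke = unname(enc$ke), voxel_size = enc$voxel_size,
                 frame_interval = enc$frame_interval, n_frames = enc$n_frames,
                 format = format, mag_scale = mag_scale,
                 phase_scaled_01 = (format == "tiff"))
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, params = file.path(dir, "params.json")))
}

#' Read a DENSE series from image stacks
#'
#' @param magnitude,phase_x,phase_y file paths (NIfTI or TIFF).
#' @param encoding a [dense_encoding()]; when `NULL` the `params.json`
#'   sidecar next to `magnitude` is consulted.
#' @param phase_units `"radians"` (default) or `"degrees"`; degrees are
#'   converted and re-wrapped.
#' @param phase_scale optional multiplicative factor applied to the stored
#'   phase values before wrapping (vendor integer scalings); for TIFF stacks
#'   written by [write_dense_series()] the `[0, 1]` scaling is undone
#'   automatically via the sidecar.
#' @return A validated [dense_series()].
#' @export
read_dense_series <- function(magnitude, phase_x, phase_y, encoding = NULL,
                              phase_units = c("radians", "degrees"),
                              phase_scale = NULL) {
  phase_units <- match.arg(phase_units)
  sidecar_path <- file.path(dirname(magnitude), "params.json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else NULL
  if (is.null(encoding)) {
    if (is.null(sidecar))
      .stopf("no 'encoding' supplied and no params.json sidecar found near %s", magnitude)
    encoding <- dense_encoding(ke = sidecar$ke, voxel_size = sidecar$voxel_size,
                               frame_interval = sidecar$frame_interval,
                               n_frames = sidecar$n_frames)
  }
  mag <- .read_stack(magnitude)
  phx <- .read_stack(phase_x)
  phy <- .read_stack(phase_y)
  if (!identical(dim(mag), dim(phx)) || !identical(dim(mag), dim(phy)))
    .stopf("shape mismatch between stacks: %s / %s / %s",
           paste(dim(mag), collapse = "x"), paste(dim(phx), collapse = "x"),
           paste(dim(phy), collapse = "x"))
  if (isTRUE(sidecar$phase_scaled_01) && .stack_format(magnitude) == "tiff") {
    mag <- mag * sidecar$mag_scale
    phx <- .wrap_phase(phx * 2 * pi - pi)
    phy <- .wrap_phase(phy * 2 * pi - pi)
  }
  if (!is.null(phase_scale)) {
    phx <- .wrap_phase(phx * phase_scale)
    phy <- .wrap_phase(phy * phase_scale)
  }
  if (phase_units == "degrees") {
    phx <- .wrap_phase(phx * pi / 180)
    phy <- .wrap_phase(phy * pi / 180)
  }
  dense_series(mag, phx, phy, encoding)
}

#' Read wall contours from JSON or CSV
#'
#' JSON schema: `{"frames": [{"frame": 1, "luminal": [[x, y], ...],
#' "adventitial": [[x, y], ...]}, ...]}`. CSV schema: columns `frame`,
#' `boundary` (`"luminal"` / `"adventitial"`), `x`, `y` (mm), UTF-8 with
#' `.` decimal and a header row.
#'
#' @param path file path (`.json` or `.csv`).
#' @param n_frames expected frame count; an error lists any missing frames.
#' @return A validated [wall_contours()] object.
#' @export
read_contours <- function(path, n_frames) {
  if (!file.exists(path)) .stopf("unreadable file: %s", path)
  n_frames <- as.integer(n_frames)
  lum <- adv <- vector("list", n_frames)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    frames <- doc$frames
    if (is.null(frames)) .stopf("%s: no 'frames' element", path)
    ids <- as.integer(frames$frame)
    for (k in seq_along(ids)) {
      t <- ids[k]
      if (t < 1L || t > n_frames) next
      lum[[t]] <- .as_points(frames$luminal[[k]])
      adv[[t]] <- .as_points(frames$adventitial[[k]])
    }
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("frame", "boundary", "x", "y")
    if (!all(need %in% names(df)))
      .stopf("%s: CSV must have columns %s", path, paste(need, collapse = ", "))
    for (t in intersect(unique(df$frame), seq_len(n_frames))) {
      sub <- df[df$frame == t, ]
      l <- sub[sub$boundary == "luminal", c("x", "y")]
      a <- sub[sub$boundary == "adventitial", c("x", "y")]
      if (nrow(l)) lum[[t]] <- as.matrix(l)
      if (nrow(a)) adv[[t]] <- as.matrix(a)
    }
  } else .stopf("unsupported contour format: %s (use .json or .csv)", path)
  missing <- which(vapply(seq_len(n_frames),
                          function(t) is.null(lum[[t]]) || is.null(adv[[t]]),
                          logical(1L)))
  if (length(missing))
    .stopf("%s: missing contours for frame(s) %s", path,
           paste(missing, collapse = ", "))
  wall_contours(lum, adv)
}

#' Write wall contours to JSON or CSV
#'
#' @param contours a [wall_contours()] object.
#' @param path output path (`.json` or `.csv`); schema as [read_contours()].
#' @return Invisibly, `path`.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "wall_contours"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    frames <- lapply(seq_len(contours$n_frames), function(t)
      list(frame = t, luminal = contours$luminal[[t]],
           adventitial = contours$adventitial[[t]]))
    jsonlite::write_json(list(frames = frames), path, digits = NA,
                         auto_unbox = TRUE, matrix = "rowmajor")
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(seq_len(contours$n_frames), function(t) {
      rbind(data.frame(frame = t, boundary = "luminal",
                       x = contours$luminal[[t]][, 1L], y = contours$luminal[[t]][, 2L]),
            data.frame(frame = t, boundary = "adventitial",
                       x = contours$adventitial[[t]][, 1L], y = contours$adventitial[[t]][, 2L]))
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  } else .stopf("unsupported contour format: %s (use .json or .csv)", path)
  invisible(path)
}

#' Write the sector strain table and summary sidecar
#'
#' One CSV row per sector (AVI numbering): sector index, circumferential
#' strain at every frame, strain at local systole, and NCS; plus a JSON
#' sidecar with the scalar summary (systole frame, mean strain,
#' heterogeneity index, displacement angle, geometry, conventions).
#'
#' @param fit a [dense_strain()] result.
#' @param path CSV output path.
#' @param summary_path JSON sidecar path; default replaces `.csv` with
#'   `_summary.json`.
#' @return Invisibly, `c(path, summary_path)`.
#' @export
write_sector_table <- function(fit, path,
                               summary_path = sub("\\.csv$", "_summary.json", path)) {
  stopifnot(inherits(fit, "dense_strain"))
  map <- fit$map
  sm <- fit$summary
  nt <- ncol(map$strain)
  df <- data.frame(sector = seq_len(map$n_sectors))
  for (t in seq_len(nt)) df[[sprintf("strain_t%02d", t)]] <- map$strain[, t]
  df$strain_systole <- map$strain[, sm$systole_frame]
  df$ncs <- sm$ncs
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(.summary_as_list(sm), summary_path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(path, summary_path))
}

.summary_as_list <- function(sm) {
  list(systole_frame = sm$systole_frame,
       mean_strain_systole = sm$mean_strain_systole,
       ncs = sm$ncs, max_ncs = sm$max_ncs,
       max_ncs_sector = sm$max_ncs_sector, max_ncs_frame = sm$max_ncs_frame,
       peak_sector = sm$peak_sector,
       peak_sector_offset_from_avi = sm$peak_sector_offset_from_avi,
       het_index = sm$het_index,
       mean_disp_angle_deg = sm$mean_disp_angle_deg,
       disp_magnitude_mm = sm$disp_magnitude_mm,
       diameter_cm = sm$diameter_cm, relative_size = sm$relative_size,
       n_valid_sectors = sm$n_valid_sectors, location = sm$location,
       conventions = sm$conventions)
}

#' Read back a sector strain table
#'
#' @param path CSV written by [write_sector_table()].
#' @param summary_path optional JSON sidecar path (read when it exists).
#' @return list with `table` (data frame), `strain` (sectors x frames
#'   matrix), `ncs`, and `summary` (list or `NULL`).
#' @export
read_sector_table <- function(path,
                              summary_path = sub("\\.csv$", "_summary.json", path)) {
  df <- utils::read.csv(path)
  scols <- grep("^strain_t[0-9]+$", names(df), value = TRUE)
  strain <- as.matrix(df[, scols])
  dimnames(strain) <- list(sector = df$sector, frame = seq_along(scols))
  summary <- if (file.exists(summary_path))
    jsonlite::read_json(summary_path, simplifyVector = TRUE) else NULL
  list(table = df, strain = strain, ncs = df$ncs, summary = summary)
}
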