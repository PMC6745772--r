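#' Displacement-encoding parameters
#'
#' @param ke displacement encoding frequency, cycles/mm; scalar or a length-2
#'   vector `(x, y)`. The in vivo protocol this pipeline targets used
#'   0.25 cyc/mm at the abdominal and mid-thoracic aorta and 0.17 cyc/mm at
#'   the distal arch.
#' @param voxel_size in-plane voxel size, mm (isotropic).
#' @param frame_interval frame spacing, ms.
#' @param n_frames number of cine frames (>= 2).
#' @return An object of class `dense_encoding`.
#' @export
dense_encoding <- function(ke = 0.25, voxel_size = 1.0,
                           frame_interval = 32, n_frames = 18L) {
  if (!is.numeric(ke) || !length(ke) %in% c(1L, 2L) || any(ke <= 0) ||
      any(!is.finite(ke)))
    .stopf("invalid 'ke': encoding frequency must be positive (cyc/mm)")
  if (length(ke) == 1L) ke <- c(ke, ke)
  names(ke) <- c("x", "y")
  if (!.is_number(voxel_size) || voxel_size <= 0)
    .stopf("invalid 'voxel_size': must be > 0 mm")
  if (!.is_number(frame_interval) || frame_interval <= 0)
    .stopf("invalid 'frame_interval': must be > 0 ms")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L)
    .stopf("invalid 'n_frames': need at least 2 frames")
  structure(list(ke = ke, voxel_size = voxel_size,
                 frame_interval = frame_interval, n_frames = n_frames),
            class = "dense_encoding")
}

#' @export
print.dense_encoding <- function(x, ...) {
  cat(sprintf("DENSE encoding: ke = (%.3f, %.3f) cyc/mm, voxel %.2f mm, %d frames every %.0f ms\n",
              x$ke[1], x$ke[2], x$voxel_size, x$n_frames, x$frame_interval))
  invisible(x)
}

#' DENSE cine phase series
#'
#' Container for one DENSE acquisition: a magnitude stack plus the wrapped
#' x- and y-encoded phase stacks, each `H x W x n_frames`, with phases in
#' `(-pi, pi]`.
#'
#' @param magnitude,phase_x,phase_y 3-D numeric arrays with identical
#'   dimensions; phases in radians wrapped to `(-pi, pi]`.
#' @param encoding a [dense_encoding()] object; `n_frames` must match the
#'   third array dimension.
#' @return An object of class `dense_series`.
#' @export
dense_series <- function(magnitude, phase_x, phase_y, encoding) {
  stopifnot(inherits(encoding, "dense_encoding"))
  dims <- dim(magnitude)
  if (is.null(dims) || length(dims) != 3L)
    .stopf("'magnitude' must be a 3-D array (H x W x frames)")
  if (!identical(dim(phase_x), dims) || !identical(dim(phase_y), dims))
    .stopf("shape mismatch: magnitude %s, phase_x %s, phase_y %s",
           paste(dims, collapse = "x"),
           paste(dim(phase_x), collapse = "x"),
           paste(dim(phase_y), collapse = "x"))
  if (dims[3L] != encoding$n_frames)
    .stopf("shape mismatch: %d frames in arrays but encoding declares %d",
           dims[3L], encoding$n_frames)
  for (nm in c("phase_x", "phase_y")) {
    ph <- get(nm)
    if (!is.numeric(ph) || any(!is.finite(ph)))
      .stopf("'%s' must be finite numeric", nm)
    rng <- range(ph)
    if (rng[1L] <= -pi - 1e-6 || rng[2L] > pi + 1e-6)
      .stopf("'%s' outside (-pi, pi]: range [%.4f, %.4f]; declare units or scale on read",
             nm, rng[1L], rng[2L])
  }
  # forgive float-boundary values only
  phase_x[phase_x <= -pi] <- pi
  phase_y[phase_y <= -pi] <- pi
  phase_x[phase_x > pi] <- pi
  phase_y[phase_y > pi] <- pi
  structure(list(magnitude = magnitude, phase_x = phase_x, phase_y = phase_y,
                 encoding = encoding),
            class = "dense_series")
}

#' @export
print.dense_series <- function(x, ...) {
  d <- dim(x$magnitude)
  cat(sprintf("DENSE series: %d x %d voxels, %d frames\n", d[1], d[2], d[3]))
  print(x$encoding)
  invisible(x)
}

#' @export
dim.dense_series <- function(x) dim(x$magnitude)

# -- wall segmentation --------------------------------------------------------

# TRUE iff polygon P (n x 2, not closed) has no self-intersection
.polygon_simple <- function(P) {
  n <- nrow(P)
  if (n < 3L) return(FALSE)
  a <- P
  b <- P[c(2:n, 1L), , drop = FALSE]
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1L]; j <- pairs[, 2L]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross2(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross2(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

.in_polygon <- function(px, py, poly) {
  pracma::inpolygon(px, py, poly[, 1L], poly[, 2L], boundary = TRUE)
}

#' Per-frame luminal and adventitial wall contours
#'
#' @param luminal,adventitial lists (one entry per frame) of `n x 2` numeric
#'   matrices of polygon vertices in image coordinates, mm. Each adventitial
#'   polygon must strictly contain its luminal polygon and both must be
#'   simple (non-self-intersecting).
#' @param check_simple run the O(n^2) self-intersection check (default TRUE).
#' @return An object of class `wall_contours`.
#' @export
wall_contours <- function(luminal, adventitial, check_simple = TRUE) {
  if (!is.list(luminal) || !is.list(adventitial))
    .stopf("'luminal' and 'adventitial' must be lists of per-frame polygons")
  if (length(luminal) != length(adventitial))
    .stopf("frame count mismatch: %d luminal vs %d adventitial polygons",
           length(luminal), length(adventitial))
  n_frames <- length(luminal)
  for (t in seq_len(n_frames)) {
    lum <- .as_points(luminal[[t]], sprintf("luminal[[%d]]", t))
    adv <- .as_points(adventitial[[t]], sprintf("adventitial[[%d]]", t))
    if (nrow(lum) < 3L || nrow(adv) < 3L)
      .stopf("frame %d: polygons need at least 3 vertices", t)
    if (check_simple) {
      if (!.polygon_simple(lum)) .stopf("frame %d: luminal polygon self-intersects", t)
      if (!.polygon_simple(adv)) .stopf("frame %d: adventitial polygon self-intersects", t)
    }
    if (!all(.in_polygon(lum[, 1L], lum[, 2L], adv)))
      .stopf("frame %d: luminal contour not contained in adventitial contour", t)
    if (any(.in_polygon(adv[, 1L], adv[, 2L], lum)))
      .stopf("frame %d: adventitial contour lies inside luminal contour", t)
    luminal[[t]] <- lum
    adventitial[[t]] <- adv
  }
  structure(list(luminal = luminal, adventitial = adventitial,
                 n_frames = n_frames),
            class = "wall_contours")
}

#' @export
print.wall_contours <- function(x, ...) {
  cat(sprintf("Wall contours: %d frames, %d/%d vertices (luminal/adventitial)\n",
              x$n_frames, nrow(x$luminal[[1]]), nrow(x$adventitial[[1]])))
  invisible(x)
}

# mid-wall contour at frame t, resampled at n_out angles about the frame's
# own rough centroid; used for the wall centroid, sector radii and diameter
.midwall_contour <- function(contours, t = 1L, n_out = 256L) {
  lum <- contours$luminal[[t]]
  adv <- contours$adventitial[[t]]
  c0 <- (colMeans(lum) + colMeans(adv)) / 2
  th <- .wrap_phase(seq(0, 2 * pi, length.out = n_out + 1L)[-(n_out + 1L)])
  rl <- .periodic_interp(.anat_angle(lum[, 1L] - c0[1L], lum[, 2L] - c0[2L]),
                         sqrt((lum[, 1L] - c0[1L])^2 + (lum[, 2L] - c0[2L])^2), th)
  ra <- .periodic_interp(.anat_angle(adv[, 1L] - c0[1L], adv[, 2L] - c0[2L]),
                         sqrt((adv[, 1L] - c0[1L])^2 + (adv[, 2L] - c0[2L])^2), th)
  rm <- (rl + ra) / 2
  u <- .anat_unit(th)
  list(points = cbind(c0[1L] + rm * u[, 1L], c0[2L] + rm * u[, 2L]),
       theta = th, radius = rm, center = c0)
}
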