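# Internal angle and geometry helpers.
#
# Image coordinates are in mm with the origin at the image corner, x rightward
# (patient-left in standard transverse display) and y downward (posterior).
# All sector arithmetic uses the "anatomical angle": 0 points left-lateral
# (+x) and angles increase counterclockwise in the axial view (anterior up).
# Because image y runs posterior, the anatomical angle of an image-space
# offset (dx, dy) is atan2(-dy, dx).

# wrap to (-pi, pi], boundary mapped to +pi
.wrap_phase <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

.anat_angle <- function(dx, dy) atan2(-dy, dx)

# unit vector (image xy) pointing at anatomical angle theta
.anat_unit <- function(theta) cbind(cos(theta), -sin(theta))

# counterclockwise (anatomical) tangent at anatomical angle theta, image xy
.anat_tangent <- function(theta) cbind(-sin(theta), -cos(theta))

.sector_width <- function(n_sectors) 2 * pi / n_sectors

# Sector bin for anatomical angle theta about the centroid: bin j covers the
# half-open arc ((j-1)*w, j*w], so a point exactly on a boundary belongs to
# the clockwise bin.
.sector_bin <- function(theta, n_sectors) {
  w <- .sector_width(n_sectors)
  m <- theta %% (2 * pi)
  j <- ceiling(m / w)
  j[j < 1L] <- n_sectors
  j[j > n_sectors] <- n_sectors
  as.integer(j)
}

# First bin counterclockwise from the aorto-vertebral interface angle: this
# bin is relabelled sector 1 (an AVI exactly on a bin boundary yields the
# next counterclockwise bin).
.avi_first_bin <- function(avi_angle, n_sectors) {
  w <- .sector_width(n_sectors)
  m <- avi_angle %% (2 * pi)
  j <- floor(m / w) + 1L
  if (j > n_sectors) j <- 1L
  as.integer(j)
}

# AVI label for internal bin j (internal bins are anchored at anatomical 0)
.avi_label <- function(j, avi_angle, n_sectors) {
  j1 <- .avi_first_bin(avi_angle, n_sectors)
  ((as.integer(j) - j1) %% n_sectors) + 1L
}

# voxel-center lattice of an H x W grid, mm; linear index is column-major
# (matches R array storage: i = row + (col-1)*H)
.voxel_centers <- function(grid_dim, voxel_size) {
  H <- grid_dim[1]; W <- grid_dim[2]
  row <- rep(seq_len(H), times = W)
  col <- rep(seq_len(W), each = H)
  list(
    ij  = cbind(row = row, col = col),
    pos = cbind(x = (col - 0.5) * voxel_size, y = (row - 0.5) * voxel_size)
  )
}

# periodic linear interpolation of radius-vs-angle samples, angles in (-pi,pi]
.periodic_interp <- function(theta_known, r_known, theta_query) {
  o <- order(theta_known)
  th <- theta_known[o]; r <- r_known[o]
  stats::approx(c(th - 2 * pi, th, th + 2 * pi), rep(r, 3),
                xout = theta_query, rule = 2)$y
}

# circular distance between sector indices on an n-sector map
.circ_sector_dist <- function(a, b, n_sectors) {
  d <- abs(a - b) %% n_sectors
  pmin(d, n_sectors - d)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.as_points <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 2L) .stopf("'%s' must be an n x 2 matrix", what)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L || !is.numeric(x)) .stopf("'%s' must be an n x 2 numeric matrix", what)
  storage.mode(x) <- "double"
  unname(x)
}
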