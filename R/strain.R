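#' Green-Lagrange strain of a bilinear quadrilateral element
#'
#' Computes the referential displacement gradient
#' \eqn{H = (\sum_a u_a \otimes \nabla N_a)\,J^{-1}} from four nodal
#' displacements via bilinear shape functions on normalized coordinates
#' \eqn{(\xi, \eta) \in [-1, 1]^2} (\eqn{J} is the reference Jacobian), and
#' the Green strain \eqn{E = (H + H^T + H^T H)/2}, evaluated at the element
#' center by default.
#'
#' @param nodes_ref 4 x 2 matrix of node positions in the reference
#'   configuration, mm, ordered counterclockwise in normalized coordinates:
#'   `(-1,-1), (1,-1), (1,1), (-1,1)`.
#' @param nodes_disp 4 x 2 matrix of nodal displacements, mm.
#' @param xi,eta evaluation point in normalized coordinates (default center).
#' @return list with `E` (2 x 2 symmetric Green strain), `H` (displacement
#'   gradient), `J` (reference Jacobian) and `detJ`.
#' @examples
#' nodes <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' green_strain_element(nodes, 0.1 * nodes)$E   # 10% biaxial -> 0.105 * I
#' @export
green_strain_element <- function(nodes_ref, nodes_disp, xi = 0, eta = 0) {
  nodes_ref <- .as_points(nodes_ref, "nodes_ref")
  nodes_disp <- .as_points(nodes_disp, "nodes_disp")
  if (nrow(nodes_ref) != 4L || nrow(nodes_disp) != 4L)
    .stopf("element needs exactly 4 nodes")
  xs <- c(-1, 1, 1, -1)
  es <- c(-1, -1, 1, 1)
  dN <- cbind(xs * (1 + es * eta) / 4, es * (1 + xs * xi) / 4)  # 4 x 2
  J <- t(nodes_ref) %*% dN                                      # dX_i/dxi_j
  detJ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  if (!is.finite(detJ) || abs(detJ) < 1e-12)
    .stopf("degenerate element: singular reference Jacobian (det = %g)", detJ)
  G <- dN %*% solve(J)                                          # grad N_a wrt X
  H <- t(nodes_disp) %*% G
  E <- (H + t(H) + t(H) %*% H) / 2
  list(E = E, H = H, J = J, detJ = detJ)
}

#' Rotate a 2-D strain tensor to radial-circumferential axes
#'
#' @param E 2 x 2 strain tensor in image (x, y) axes.
#' @param tangent_angle direction of the local wall tangent in image-plane
#'   radians (`atan2(ty, tx)`), oriented counterclockwise in the anatomical
#'   view; the radial axis is the tangent rotated +90 degrees (outward for a
#'   counterclockwise-oriented wall).
#' @return list with `E_rr`, `E_rt`, `E_tt` and the rotated tensor
#'   `E_cyl` (axes radial, circumferential). The rotation preserves trace
#'   and determinant.
#' @export
rotate_to_cylindrical <- function(E, tangent_angle) {
  stopifnot(is.matrix(E), all(dim(E) == 2L))
  tv <- c(cos(tangent_angle), sin(tangent_angle))
  rv <- c(-tv[2L], tv[1L])
  R <- cbind(rv, tv)
  Ec <- t(R) %*% E %*% R
  list(E_rr = Ec[1, 1], E_rt = Ec[1, 2], E_tt = Ec[2, 2], E_cyl = Ec)
}

#' Build per-sector quadrilateral elements from tracked trajectories
#'
#' Partitions the tracked reference voxels into 16 equal circumferential
#' sectors about the reference-frame wall centroid (mean of the mid-wall
#' contour at frame 1) and, within each sector, into four quadrants:
#' inner/outer half of the wall crossed with the clockwise/counterclockwise
#' half of the arc. Each quadrant's voxels are averaged into one node
#' (reference-point averaging); the node's motion is the mean trajectory of
#' its voxels (weighted spatial averaging with weights implicit in the voxel
#' counts). Sectors with an empty quadrant, fewer than 4 voxels, or a
#' near-degenerate reference quadrilateral (Jacobian condition number above
#' 1e6) are flagged invalid.
#'
#' @param traj a `trajectory_field` from [track_forward()].
#' @param contours a [wall_contours()] object (frame 1 defines the geometry).
#' @param n_sectors number of sectors (default 16).
#' @return An object of class `sector_elements`: per-sector node sets and
#'   validity flags, plus the wall centroid and sector center angles
#'   (internal numbering, anchored at anatomical angle 0).
#' @export
build_sector_elements <- function(traj, contours, n_sectors = 16L) {
  stopifnot(inherits(traj, "trajectory_field"), inherits(contours, "wall_contours"))
  n_sectors <- as.integer(n_sectors)
  mw <- .midwall_contour(contours, 1L)
  centroid <- colMeans(mw$points)
  w <- .sector_width(n_sectors)

  dx <- traj$X1[, 1L] - centroid[1L]
  dy <- traj$X1[, 2L] - centroid[2L]
  theta <- .anat_angle(dx, dy)
  r <- sqrt(dx^2 + dy^2)
  bin <- .sector_bin(theta, n_sectors)
  r_mid <- .periodic_interp(
    .anat_angle(mw$points[, 1L] - centroid[1L], mw$points[, 2L] - centroid[2L]),
    sqrt((mw$points[, 1L] - centroid[1L])^2 + (mw$points[, 2L] - centroid[2L])^2),
    theta)
  inner <- r <= r_mid
  within <- (theta %% (2 * pi)) - (bin - 1L) * w    # position inside bin, (0, w]
  ccw <- within > w / 2
  # quadrant order matches element corners: 1 inner-cw, 2 inner-ccw,
  # 3 outer-ccw, 4 outer-cw  (xi = circumferential, eta = radial)
  quad <- ifelse(inner, ifelse(ccw, 2L, 1L), ifelse(ccw, 3L, 4L))

  nt <- traj$n_frames
  sectors <- vector("list", n_sectors)
  for (s in seq_len(n_sectors)) {
    in_s <- bin == s
    qs <- quad[in_s]
    idx <- which(in_s)
    valid <- sum(in_s) >= 4L && all(tabulate(qs, 4L) > 0L)
    nodes_ref <- matrix(NA_real_, 4L, 2L)
    Un <- array(NA_real_, dim = c(4L, 2L, nt))
    if (valid) {
      for (a in 1:4) {
        sel <- idx[qs == a]
        nodes_ref[a, ] <- colMeans(traj$X1[sel, , drop = FALSE])
        Un[a, , ] <- apply(traj$U[sel, , , drop = FALSE], c(2L, 3L), mean)
      }
      jac <- try(green_strain_element(nodes_ref, matrix(0, 4L, 2L))$J, silent = TRUE)
      if (inherits(jac, "try-error") || kappa(jac, exact = TRUE) > 1e6)
        valid <- FALSE
    }
    if (!valid)
      .warnf("sector %d flagged invalid (%d voxels)", s, sum(in_s))
    sectors[[s]] <- list(nodes_ref = nodes_ref, U = Un, valid = valid,
                         n_voxels = sum(in_s),
                         center = if (valid) colMeans(nodes_ref) else
                           centroid + mean(mw$radius) * .anat_unit((s - 0.5) * w)[1L, ])
  }
  structure(list(sectors = sectors, centroid = centroid,
                 n_sectors = n_sectors, n_frames = nt,
                 theta_centers = (seq_len(n_sectors) - 0.5) * w),
            class = "sector_elements")
}

# full sector x frame tensor series in cylindrical axes (internal numbering);
# the wall tangent at a sector is the central difference between the two
# adjacent sector element centers in the reference configuration
.sector_strain_series <- function(elements) {
  ns <- elements$n_sectors
  nt <- elements$n_frames
  E_rr <- E_rt <- E_tt <- matrix(NA_real_, ns, nt)
  valid <- vapply(elements$sectors, `[[`, logical(1L), "valid")
  for (s in which(valid)) {
    prev <- elements$sectors[[((s - 2L) %% ns) + 1L]]
    nxt <- elements$sectors[[(s %% ns) + 1L]]
    th_s <- elements$theta_centers[s]
    tv_analytic <- .anat_tangent(th_s)[1L, ]
    tv <- nxt$center - prev$center
    if (sqrt(sum(tv^2)) < 1e-9) tv <- tv_analytic
    if (sum(tv * tv_analytic) < 0) tv <- -tv      # orient counterclockwise
    ang <- atan2(tv[2L], tv[1L])
    el <- elements$sectors[[s]]
    for (t in seq_len(nt)) {
      gs <- green_strain_element(el$nodes_ref, el$U[, , t])
      rc <- rotate_to_cylindrical(gs$E, ang)
      E_rr[s, t] <- rc$E_rr; E_rt[s, t] <- rc$E_rt; E_tt[s, t] <- rc$E_tt
    }
  }
  list(E_rr = E_rr, E_rt = E_rt, E_tt = E_tt, valid = valid)
}

#' Assemble the AVI-numbered 16-sector strain map
#'
#' Computes per-sector Green strain tensors over all frames from the sector
#' elements, rotates them to radial-circumferential axes, renumbers sectors
#' so that sector 1 is the first sector counterclockwise from the
#' aorto-vertebral interface (an AVI exactly on a sector boundary yields the
#' next counterclockwise sector), and time-smooths each sector's series with
#' a fifth-order polynomial. The scan is rejected when fewer than 12 of 16
#' sectors are valid (mirroring in vivo exclusion of poor-signal scans);
#' invalid sectors carry `NA`.
#'
#' @param elements a `sector_elements` object from [build_sector_elements()].
#' @param avi_angle anatomical angle of the aorto-vertebral interface about
#'   the wall centroid, radians.
#' @param location aortic location label: `"IAA"`, `"DTA"` or `"DAA"`.
#' @param strain_smooth apply [polynomial_smooth_strain()] (default TRUE;
#'   requires at least 7 frames).
#' @return An object of class `sector_strain_map` with matrices `strain`
#'   (circumferential Green strain, sectors x frames, AVI-numbered), `E_rr`,
#'   `E_rt`, logical `valid`, `sector_centers` (anatomical angles),
#'   `avi_angle`, `avi_sector_offset`, `n_valid`, `location`.
#' @export
assemble_sector_map <- function(elements, avi_angle = 0, location = "DTA",
                                strain_smooth = TRUE) {
  stopifnot(inherits(elements, "sector_elements"))
  location <- match.arg(location, c("IAA", "DTA", "DAA"))
  ser <- .sector_strain_series(elements)
  ns <- elements$n_sectors
  n_valid <- sum(ser$valid)
  if (n_valid < ceiling(0.75 * ns))
    .stopf("scan quality insufficient: only %d of %d sectors valid", n_valid, ns)

  lab <- .avi_label(seq_len(ns), avi_angle, ns)
  reorder <- function(M) { out <- M; out[lab, ] <- M; out }
  strain <- reorder(ser$E_tt)
  E_rr <- reorder(ser$E_rr)
  E_rt <- reorder(ser$E_rt)
  valid <- logical(ns); valid[lab] <- ser$valid
  centers <- numeric(ns); centers[lab] <- elements$theta_centers

  if (strain_smooth) {
    strain <- polynomial_smooth_strain(strain)
    E_rr <- polynomial_smooth_strain(E_rr)
    E_rt <- polynomial_smooth_strain(E_rt)
  }
  rownames(strain) <- rownames(E_rr) <- rownames(E_rt) <- seq_len(ns)

  structure(list(strain = strain, E_rr = E_rr, E_rt = E_rt, valid = valid,
                 sector_centers = centers, avi_angle = avi_angle,
                 avi_sector_offset = .avi_first_bin(avi_angle, ns) - 1L,
                 n_valid = n_valid, n_sectors = ns,
                 centroid = elements$centroid, location = location,
                 smoothed = isTRUE(strain_smooth)),
            class = "sector_strain_map")
}

#' @export
print.sector_strain_map <- function(x, ...) {
  cat(sprintf("Sector strain map (%s): %d sectors x %d frames, %d valid, AVI offset %d\n",
              x$location, x$n_sectors, ncol(x$strain), x$n_valid, x$avi_sector_offset))
  invisible(x)
}
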