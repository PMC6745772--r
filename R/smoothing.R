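#' Spatially smooth the displacement field over the wall
#'
#' Replaces each wall voxel's displacement by the unweighted mean over all
#' wall voxels within a Chebyshev distance of `radius` voxel-spaces
#' (including itself); voxels outside the wall never enter the average. The
#' in vivo protocol used a radius of 1 voxel-space except at the infrarenal
#' abdominal aorta, where 2 was required.
#'
#' @param back one frame of a back-displacement field (list with `ij`, `d`)
#'   or a whole `back_displacement` object, in which case every frame is
#'   smoothed.
#' @param radius 1 or 2 voxel-spaces.
#' @param grid_dim image dimensions `c(H, W)`; taken from the object when it
#'   is a `back_displacement`.
#' @return Same structure as the input with `d` replaced by smoothed values.
#' @export
spatial_smooth <- function(back, radius = 1L, grid_dim = NULL) {
  radius <- as.integer(radius)
  if (!radius %in% c(1L, 2L)) .stopf("invalid 'radius': must be 1 or 2 voxel-spaces")
  if (inherits(back, "back_displacement")) {
    back$frames <- lapply(back$frames, .spatial_smooth_frame,
                          radius = radius, grid_dim = back$grid)
    return(back)
  }
  if (is.null(grid_dim)) .stopf("'grid_dim' required when smoothing a single frame")
  .spatial_smooth_frame(back, radius, grid_dim)
}

.spatial_smooth_frame <- function(entry, radius, grid_dim) {
  H <- grid_dim[1L]; W <- grid_dim[2L]
  Dx <- Dy <- matrix(NA_real_, H, W)
  sel <- cbind(entry$ij[, 1L], entry$ij[, 2L])
  Dx[sel] <- entry$d[, 1L]
  Dy[sel] <- entry$d[, 2L]
  in_wall <- !is.na(Dx)
  sx <- sy <- cnt <- matrix(0, H, W)
  for (a in -radius:radius) {
    rs <- intersect(seq_len(H), seq_len(H) - a)     # rows with valid shifted row
    for (b in -radius:radius) {
      cs <- intersect(seq_len(W), seq_len(W) - b)
      src_r <- rs + a; src_c <- cs + b
      ok <- in_wall[src_r, src_c, drop = FALSE]
      sx[rs, cs] <- sx[rs, cs] + ifelse(ok, Dx[src_r, src_c], 0)
      sy[rs, cs] <- sy[rs, cs] + ifelse(ok, Dy[src_r, src_c], 0)
      cnt[rs, cs] <- cnt[rs, cs] + ok
    }
  }
  entry$d <- cbind(x = (sx / cnt)[sel], y = (sy / cnt)[sel])
  entry
}

#' Temporally smooth tracked positions
#'
#' Centered moving average of each trajectory coordinate over `window`
#' frames, truncated (not padded) at the series edges, after which the
#' forward displacement is re-anchored so that `u_1 = 0` exactly.
#'
#' @param traj a `trajectory_field` from [track_forward()].
#' @param window odd window length in frames; 1 is the identity.
#' @return A smoothed `trajectory_field`.
#' @export
temporal_smooth_positions <- function(traj, window = 3L) {
  stopifnot(inherits(traj, "trajectory_field"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    .stopf("invalid 'window': must be an odd positive number of frames")
  if (window > traj$n_frames)
    .stopf("invalid 'window': exceeds the %d available frames", traj$n_frames)
  if (window == 1L) return(traj)
  hw <- (window - 1L) %/% 2L
  nt <- traj$n_frames
  S <- traj$U
  for (t in seq_len(nt)) {
    lo <- max(1L, t - hw); hi <- min(nt, t + hw)
    S[, , t] <- apply(traj$U[, , lo:hi, drop = FALSE], c(1L, 2L), mean)
  }
  traj$U <- sweep(S, c(1L, 2L), S[, , 1L])   # re-anchor u_1 = 0
  traj
}

#' Fifth-order polynomial smoothing of strain time-courses
#'
#' Per sector, an ordinary least-squares polynomial of degree `degree`
#' (default 5) in the frame index is fitted to the strain series and the
#' fitted values returned. Series that are exactly polynomial of degree <=
#' `degree` are reproduced to numerical precision. Refused when fewer than
#' `degree + 2` frames are available (the fit would interpolate noise).
#'
#' @param strain numeric vector (one series) or `n_sectors x n_frames`
#'   matrix; rows that are all `NA` are passed through unchanged.
#' @param degree polynomial degree (default 5).
#' @return Smoothed series with the same shape as the input.
#' @export
polynomial_smooth_strain <- function(strain, degree = 5L) {
  degree <- as.integer(degree)
  if (degree < 1L) .stopf("invalid 'degree': must be >= 1")
  vec <- is.null(dim(strain))
  M <- if (vec) matrix(strain, nrow = 1L) else as.matrix(strain)
  nt <- ncol(M)
  if (nt < degree + 2L)
    .stopf("polynomial smoothing refused: %d frames < %d required for degree %d",
           nt, degree + 2L, degree)
  X <- cbind(1, stats::poly(seq_len(nt), degree))
  P <- X %*% solve(crossprod(X), t(X))     # symmetric projection matrix
  ok <- rowSums(is.na(M)) == 0L
  M[ok, ] <- M[ok, , drop = FALSE] %*% P
  if (vec) as.numeric(M) else M
}
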