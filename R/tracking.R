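#' Rasterize the wall segmentation to a voxel mask
#'
#' A voxel belongs to the wall when its center lies inside the adventitial
#' polygon and outside the luminal polygon (even-odd rule).
#'
#' @param contours a [wall_contours()] object.
#' @param t frame index.
#' @param grid_dim image dimensions `c(H, W)`.
#' @param voxel_size voxel size, mm.
#' @return `H x W` logical matrix.
#' @export
wall_mask <- function(contours, t, grid_dim, voxel_size) {
  stopifnot(inherits(contours, "wall_contours"))
  vc <- .voxel_centers(grid_dim, voxel_size)
  inside <- .in_polygon(vc$pos[, 1L], vc$pos[, 2L], contours$adventitial[[t]]) &
    !.in_polygon(vc$pos[, 1L], vc$pos[, 2L], contours$luminal[[t]])
  matrix(inside, grid_dim[1L], grid_dim[2L])
}

# 4-connected component labels of a logical mask (0 = background)
.label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      r <- ((v - 1L) %% H) + 1L
      cc <- ((v - 1L) %/% H) + 1L
      for (nb in c(if (r > 1L) v - 1L, if (r < H) v + 1L,
                   if (cc > 1L) v - H, if (cc < W) v + H)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# Quality-guided unwrapping of one wrapped-phase image restricted to a mask
# component set. Starts each component at its highest-quality voxel and grows
# by always admitting the highest-quality frontier voxel, adding the multiple
# of 2*pi that matches the admitting neighbor. Returns a vector over
# which(mask) in column-major order.
.unwrap_masked <- function(wrapped, mask, quality) {
  H <- nrow(mask)
  comp <- .label_components(mask)
  phi <- matrix(NA_real_, nrow(mask), ncol(mask))
  neighbors <- function(v) {
    r <- ((v - 1L) %% H) + 1L
    cc <- ((v - 1L) %/% H) + 1L
    c(if (r > 1L) v - 1L, if (r < H) v + 1L,
      if (cc > 1L) v - H, if (cc < ncol(mask)) v + H)
  }
  for (k in seq_len(comp$n)) {
    cells <- which(comp$labels == k)
    q <- quality[cells]
    seed <- cells[which.max(q)]
    phi[seed] <- wrapped[seed]
    cand_q <- rep(-Inf, length(cells))
    names(cand_q) <- cells
    cand_src <- integer(length(cells))
    pos_of <- match(seq_along(comp$labels), cells, nomatch = 0L) # sparse map
    solved <- rep(FALSE, length(cells))
    solved[match(seed, cells)] <- TRUE
    for (nb in neighbors(seed)) {
      p <- pos_of[nb]
      if (p > 0L && !solved[p]) { cand_q[p] <- quality[nb]; cand_src[p] <- seed }
    }
    n_left <- length(cells) - 1L
    while (n_left > 0L) {
      p <- which.max(cand_q)
      if (!is.finite(cand_q[p])) break # disconnected within component: cannot happen
      v <- cells[p]
      src <- cand_src[p]
      phi[v] <- wrapped[v] + 2 * pi * round((phi[src] - wrapped[v]) / (2 * pi))
      solved[p] <- TRUE
      cand_q[p] <- -Inf
      n_left <- n_left - 1L
      for (nb in neighbors(v)) {
        pp <- pos_of[nb]
        if (pp > 0L && !solved[pp]) {
          if (quality[nb] > cand_q[pp] || cand_src[pp] == 0L) {
            cand_q[pp] <- quality[nb]; cand_src[pp] <- v
          }
        }
      }
    }
  }
  list(phi = phi[which(mask)], components = comp$labels[which(mask)],
       n_components = comp$n)
}

#' Unwrap the DENSE phase pair over the wall at one frame
#'
#' 2-D spatial unwrapping restricted to the rasterized wall mask, one phase
#' channel at a time, using a magnitude-guided (quality-guided) flood fill:
#' within each connected component no unwrapped neighbor jump exceeds pi.
#' Disjoint components are unwrapped independently (with a warning) and each
#' retains its seed voxel's wrapped value, i.e. a per-component global
#' multiple of 2*pi remains undetermined; [unwrap_series()] resolves it by
#' temporal continuity.
#'
#' @param series a [dense_series()] object.
#' @param contours a [wall_contours()] object.
#' @param t frame index.
#' @return list with `ij` (voxel indices), `pos` (voxel centers, mm), `phi`
#'   (n x 2 unwrapped phase, radians), `components`, `n_components`.
#' @export
unwrap_phase <- function(series, contours, t) {
  stopifnot(inherits(series, "dense_series"), inherits(contours, "wall_contours"))
  d <- dim(series$magnitude)
  mask <- wall_mask(contours, t, d[1:2], series$encoding$voxel_size)
  if (!any(mask)) .stopf("frame %d: empty wall mask", t)
  quality <- series$magnitude[, , t]
  ux <- .unwrap_masked(series$phase_x[, , t], mask, quality)
  uy <- .unwrap_masked(series$phase_y[, , t], mask, quality)
  if (ux$n_components > 1L)
    .warnf("frame %d: wall mask has %d connected components; unwrapped independently",
           t, ux$n_components)
  sel <- which(mask)
  H <- d[1L]
  ij <- cbind(row = ((sel - 1L) %% H) + 1L, col = ((sel - 1L) %/% H) + 1L)
  pos <- cbind(x = (ij[, "col"] - 0.5) * series$encoding$voxel_size,
               y = (ij[, "row"] - 0.5) * series$encoding$voxel_size)
  list(ij = ij, pos = pos, phi = cbind(x = ux$phi, y = uy$phi),
       components = ux$components, n_components = ux$n_components)
}

#' Unwrap all frames with temporal anchoring of the 2*pi offset
#'
#' Runs [unwrap_phase()] on every frame, then fixes each frame's (and each
#' connected component's) global 2*pi offset by temporal continuity: frame 1
#' is anchored to a median phase of 0 (displacement is zero at the encoding
#' instant), and each subsequent frame adds the multiple of 2*pi that brings
#' its median phase closest to the previous frame's median. Valid whenever
#' the wall moves less than half an encoding period between frames.
#'
#' @inheritParams unwrap_phase
#' @return list of per-frame unwrap results (as [unwrap_phase()]).
#' @export
unwrap_series <- function(series, contours) {
  stopifnot(inherits(series, "dense_series"), inherits(contours, "wall_contours"))
  nt <- series$encoding$n_frames
  if (contours$n_frames != nt)
    .stopf("contours cover %d frames but series has %d", contours$n_frames, nt)
  out <- vector("list", nt)
  ref_med <- c(x = 0, y = 0)
  for (t in seq_len(nt)) {
    uw <- unwrap_phase(series, contours, t)
    for (ch in 1:2) {
      for (k in seq_len(uw$n_components)) {
        in_k <- uw$components == k
        shift <- 2 * pi * round((ref_med[ch] - stats::median(uw$phi[in_k, ch])) / (2 * pi))
        uw$phi[in_k, ch] <- uw$phi[in_k, ch] + shift
      }
    }
    ref_med <- c(stats::median(uw$phi[, 1L]), stats::median(uw$phi[, 2L]))
    out[[t]] <- uw
  }
  out
}

#' Decode unwrapped phase into displacement (mm)
#'
#' The DENSE encoding relation: \eqn{d_{i} = \varphi_{i} / (2\pi k_e)} per
#' in-plane axis.
#'
#' @param unwrapped result of [unwrap_phase()] (or any list with `phi`,
#'   `pos`, `ij`).
#' @param encoding a [dense_encoding()] object.
#' @return list with `ij`, `pos` (observed voxel positions) and `d`
#'   (n x 2 displacement, mm) — one frame of the back-displacement field.
#' @export
decode_displacement <- function(unwrapped, encoding) {
  stopifnot(inherits(encoding, "dense_encoding"))
  phi <- unwrapped$phi
  d <- cbind(x = phi[, 1L] / (2 * pi * encoding$ke[1L]),
             y = phi[, 2L] / (2 * pi * encoding$ke[2L]))
  list(ij = unwrapped$ij, pos = unwrapped$pos, d = d)
}

#' Unwrap and decode a whole series into a back-displacement field
#'
#' @inheritParams unwrap_phase
#' @return An object of class `back_displacement`: `frames` (per-frame lists
#'   with `ij`, `pos`, `d`), `encoding`, `grid`.
#' @export
decode_series <- function(series, contours) {
  uw <- unwrap_series(series, contours)
  frames <- lapply(uw, decode_displacement, encoding = series$encoding)
  structure(list(frames = frames, encoding = series$encoding,
                 grid = dim(series$magnitude)[1:2]),
            class = "back_displacement")
}

#' Track reference wall voxels forward through all frames
#'
#' Reconstructs Lagrangian trajectories from the Eulerian back-displacement
#' field. Every frame-`t` entry is back-projected to its implied reference
#' origin (observed position minus displacement); for each reference voxel
#' the three origins closest to it are found and its forward displacement is
#' the inverse-distance-weighted mean of those entries' displacements. If an
#' origin coincides with the reference voxel within 1e-9 mm that entry is
#' used alone. The reference configuration is frame 1 (the encoding instant),
#' so `u_1 = 0` for every voxel.
#'
#' @param back a `back_displacement` object from [decode_series()] (or a
#'   compatible list of frames).
#' @return An object of class `trajectory_field`: `X1` (m x 2 reference
#'   positions), `ij`, `U` (m x 2 x n_frames forward displacements),
#'   `n_frames`.
#' @export
track_forward <- function(back) {
  frames <- if (inherits(back, "back_displacement")) back$frames else back
  nt <- length(frames)
  ref <- frames[[1L]]
  X1 <- unname(ref$pos)
  m <- nrow(X1)
  U <- array(0, dim = c(m, 2L, nt))
  for (t in seq_len(nt)[-1L]) {
    e <- frames[[t]]
    n <- nrow(e$pos)
    if (n < 3L) .stopf("frame %d: tracking needs at least 3 displacement entries, found %d", t, n)
    org_x <- e$pos[, 1L] - e$d[, 1L]
    org_y <- e$pos[, 2L] - e$d[, 2L]
    D2 <- outer(X1[, 1L], org_x, "-")^2 + outer(X1[, 2L], org_y, "-")^2
    for (j in seq_len(m)) {
      d2 <- D2[j, ]
      nn <- order(d2)[1:3]
      if (d2[nn[1L]] < 1e-18) {            # exact hit: use that entry alone
        U[j, , t] <- e$d[nn[1L], ]
      } else {
        wgt <- 1 / sqrt(d2[nn])
        wgt <- wgt / sum(wgt)
        U[j, 1L, t] <- sum(wgt * e$d[nn, 1L])
        U[j, 2L, t] <- sum(wgt * e$d[nn, 2L])
      }
    }
  }
  structure(list(X1 = X1, ij = ref$ij, U = U, n_frames = nt),
            class = "trajectory_field")
}

#' Tracked positions at a frame
#'
#' @param traj a `trajectory_field` object.
#' @param t frame index.
#' @return m x 2 matrix `X1 + u_t`.
#' @export
tracked_positions <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory_field"))
  traj$X1 + traj$U[, , t]
}

#' Superpose a rigid-body motion on tracked configurations
#'
#' Applies `x -> R(angle) (x - center) + center + translation` to the tracked
#' positions at every frame after the reference (frame 1 is left untouched)
#' and recomputes the forward displacements. Green strain is objective, so a
#' sector strain map computed from the modified trajectories must be
#' unchanged to numerical precision — a standard check of the strain code.
#'
#' @param traj a `trajectory_field`.
#' @param angle rotation angle, radians (image-plane).
#' @param translation length-2 translation, mm.
#' @param center rotation center, mm; defaults to the reference centroid.
#' @return The modified `trajectory_field`.
#' @export
superpose_rigid <- function(traj, angle = 0, translation = c(0, 0),
                            center = colMeans(traj$X1)) {
  stopifnot(inherits(traj, "trajectory_field"))
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  for (t in seq_len(traj$n_frames)[-1L]) {
    Xt <- traj$X1 + traj$U[, , t]
    Xt <- sweep(sweep(Xt, 2L, center) %*% t(R), 2L, -(center + translation))
    traj$U[, , t] <- Xt - traj$X1
  }
  traj
}

#' @export
print.trajectory_field <- function(x, ...) {
  cat(sprintf("Trajectory field: %d wall voxels over %d frames\n",
              nrow(x$X1), x$n_frames))
  invisible(x)
}
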