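# Internal geometry and array helpers shared across modules.

#' Build a diagonal scanner affine from voxel sizes
#'
#' Maps 0-based voxel indices to mm. The slice pitch (third voxel size)
#' should include any inter-slice gap.
#'
#' @param voxel_size numeric length-3, mm per voxel along x, y, z.
#' @return 4x4 affine matrix.
#' @export
voxel_affine <- function(voxel_size) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  a <- diag(c(voxel_size, 1))
  a
}

# mm coordinates of all voxel centers, N x 3, voxel indices 0-based
voxel_centers_mm <- function(dm, affine) {
  g <- as.matrix(expand.grid(x = seq_len(dm[1]) - 1L,
                             y = seq_len(dm[2]) - 1L,
                             z = seq_len(dm[3]) - 1L))
  xyz1 <- cbind(g, 1)
  mm <- xyz1 %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

# Rotation matrix from degrees about x, y, z (applied Rz %*% Ry %*% Rx)
rotation_matrix <- function(rx_deg, ry_deg, rz_deg) {
  a <- rx_deg * pi / 180; b <- ry_deg * pi / 180; c <- rz_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

# Trilinear interpolation of a 3D volume at fractional 0-based voxel
# coordinates (N x 3). Coordinates outside the grid sample zero.
trilinear_sample <- function(vol, ijk) {
  d <- dim(vol)
  n <- nrow(ijk)
  i0 <- floor(ijk)
  f <- ijk - i0
  out <- numeric(n)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
         (if (dj) f[, 2] else 1 - f[, 2]) *
         (if (dk) f[, 3] else 1 - f[, 3])
    ii <- i0[, 1] + di; jj <- i0[, 2] + dj; kk <- i0[, 3] + dk
    ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3] & w > 0
    if (any(ok)) {
      idx <- ii[ok] + d[1] * (jj[ok] + d[2] * kk[ok]) + 1
      out[ok] <- out[ok] + w[ok] * vol[idx]
    }
  }
  out
}

#' Resample a volume under a rigid-body transform
#'
#' The transform moves a point p (mm) to `R (p - c) + c + t`, with rotations
#' about the volume center `c`. With `invert = FALSE` the returned volume is
#' the input as seen after the motion (the object moves); `invert = TRUE`
#' undoes a motion of the given parameters.
#'
#' @param vol 3D array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param params length-6: translations x,y,z in mm then rotations x,y,z in
#'   degrees.
#' @param invert logical; apply the inverse transform.
#' @return resampled 3D array (zero outside the original field of view).
#' @export
resample_rigid <- function(vol, affine, params, invert = FALSE) {
  stopifnot(length(params) == 6)
  if (all(params == 0)) return(vol)
  d <- dim(vol)
  rot <- rotation_matrix(params[4], params[5], params[6])
  tr <- params[1:3]
  ctr_vox <- (d - 1) / 2
  ctr <- as.numeric(affine %*% c(ctr_vox, 1))[1:3]
  mm <- voxel_centers_mm(d, affine)
  if (invert) {
    # source point of output voxel under the forward transform
    src <- sweep(mm, 2, ctr) %*% t(rot)
    src <- sweep(src, 2, ctr + tr, FUN = "+")
  } else {
    src <- sweep(sweep(mm, 2, tr), 2, ctr) %*% rot   # R^T (p - t - c)
    src <- sweep(src, 2, ctr, FUN = "+")
  }
  ainv <- solve(affine)
  ijk <- cbind(src, 1) %*% t(ainv)
  array(trilinear_sample(vol, ijk[, 1:3, drop = FALSE]), dim = d)
}

# Largest 6-connected component of a logical 3D mask, by iterative frontier
# dilation (no external image library needed at this scale).
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  remaining <- which(mask & lab == 0L)
  shift_idx <- function(idx, axis, by) {
    coord <- arrayInd(idx, d)
    coord[, axis] <- coord[, axis] + by
    ok <- coord[, axis] >= 1 & coord[, axis] <= d[axis]
    coord <- coord[ok, , drop = FALSE]
    (coord[, 1] + d[1] * (coord[, 2] - 1) + d[1] * d[2] * (coord[, 3] - 1))
  }
  while (length(remaining) > 0) {
    cur <- cur + 1L
    frontier <- remaining[1]
    lab[frontier] <- cur
    while (length(frontier) > 0) {
      nb <- integer(0)
      for (axis in 1:3) for (by in c(-1L, 1L)) {
        nb <- c(nb, shift_idx(frontier, axis, by))
      }
      nb <- unique(nb)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
    remaining <- which(mask & lab == 0L)
  }
  if (cur == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = cur)
  lab == which.max(sizes)
}

# quantile-based robust maximum used by masking and M0 flooring
robust_max <- function(x, prob = 0.98) {
  stats::quantile(as.numeric(x), probs = prob, names = FALSE, na.rm = TRUE)
}
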