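# Denoising chain: motion correction -> spatial smoothing -> temporal
# high-pass filtering -> nuisance regression. The order is fixed; each step
# preserves the grid.

# --- spatial smoothing ------------------------------------------------------

# Dense banded convolution matrix for a 1D sampled Gaussian kernel,
# zero-padded at the edges (rows near the boundary sum to < 1).
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- -r:r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  km <- matrix(0, n, n)
  for (j in seq_along(off)) {
    i <- seq_len(n)
    ii <- i + off[j]
    ok <- ii >= 1 & ii <= n
    km[cbind(i[ok], ii[ok])] <- km[cbind(i[ok], ii[ok])] + k[j]
  }
  km
}

# separable 3D Gaussian smoothing, sigma per axis in voxels
gauss_smooth_volume <- function(vol, sigma_vox) {
  d <- dim(vol)
  if (sigma_vox[1] > 0) {
    vol <- array(gauss_kernel_matrix(d[1], sigma_vox[1]) %*%
                   matrix(vol, d[1]), dim = d)
  }
  if (sigma_vox[2] > 0) {
    v <- aperm(vol, c(2, 1, 3))
    v <- array(gauss_kernel_matrix(d[2], sigma_vox[2]) %*%
                 matrix(v, d[2]), dim = c(d[2], d[1], d[3]))
    vol <- aperm(v, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    v <- aperm(vol, c(3, 1, 2))
    v <- array(gauss_kernel_matrix(d[3], sigma_vox[3]) %*%
                 matrix(v, d[3]), dim = c(d[3], d[1], d[2]))
    vol <- aperm(v, c(2, 3, 1))
  }
  vol
}

#' Isotropic Gaussian spatial smoothing
#'
#' Per-volume 3D convolution with an isotropic Gaussian of the requested
#' full-width-at-half-maximum in mm, converted to voxel units per axis
#' (`sigma = fwhm / (2 sqrt(2 ln 2))`). The kernel is sampled at integer
#' voxel offsets and normalized to unit sum; boundaries are zero-padded
#' (no reflection), so totals are conserved only away from the edges.
#'
#' @param x an `asl_series` or a 3D array.
#' @param fwhm_mm kernel FWHM in mm (default 4).
#' @param voxel_size mm per voxel for plain arrays; taken from the affine
#'   for an `asl_series`.
#' @return object of the same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 4, voxel_size = NULL) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  if (inherits(x, "asl_series")) {
    vx <- abs(diag(x$affine)[1:3])
    sig <- sigma_mm / vx
    out <- x
    for (v in seq_len(dim(x$data)[4])) {
      out$data[, , , v] <- gauss_smooth_volume(x$data[, , , v], sig)
    }
    out
  } else {
    stopifnot(is.array(x), length(dim(x)) == 3, !is.null(voxel_size))
    gauss_smooth_volume(x, sigma_mm / voxel_size)
  }
}

# --- temporal filtering -----------------------------------------------------

#' Zero-phase Butterworth high-pass temporal filtering
#'
#' A second-order Butterworth high-pass (default cutoff 0.01 Hz) applied
#' forward and backward (zero phase) to every voxel timecourse of the
#' non-M0 volumes. The per-voxel temporal mean is re-added after filtering
#' so that the absolute intensity scale -- and hence M0-relative
#' quantification -- is preserved. The M0 volume is left untouched.
#'
#' @param series an `asl_series` (or a plain matrix, time in columns).
#' @param cutoff_hz high-pass cutoff frequency (Hz); must be below Nyquist.
#' @param order filter order (default 2).
#' @param tr_ms sampling interval for plain matrices.
#' @return filtered object of the same type.
#' @export
highpass_butterworth <- function(series, cutoff_hz = 0.01, order = 2,
                                 tr_ms = NULL) {
  if (inherits(series, "asl_series")) tr_ms <- series$tr_ms
  stopifnot(!is.null(tr_ms), tr_ms > 0, cutoff_hz > 0, order >= 1)
  fs <- 1000 / tr_ms
  if (cutoff_hz >= fs / 2) {
    stop("cutoff frequency must be below the Nyquist frequency ",
         signif(fs / 2, 4), " Hz")
  }
  if (inherits(series, "asl_series")) {
    idx <- which(series$volume_labels != "m0")
    nt <- length(idx)
    if (nt < 8) stop("need at least 8 time points to filter")
    fop <- filtfilt_operator(order, cutoff_hz / (fs / 2), nt)
    d <- dim(series$data)
    y <- matrix(series$data[, , , idx], ncol = nt)
    mu <- rowMeans(y)
    yf <- (y - mu) %*% t(fop) + mu
    out <- series
    out$data[, , , idx] <- array(yf, dim = c(d[1:3], nt))
    out
  } else {
    y <- as.matrix(series)
    nt <- ncol(y)
    if (nt < 8) stop("need at least 8 time points to filter")
    fop <- filtfilt_operator(order, cutoff_hz / (fs / 2), nt)
    mu <- rowMeans(y)
    (y - mu) %*% t(fop) + mu
  }
}

# filtfilt is linear in its input for fixed length, so materialize it as a
# T x T operator (applied to unit vectors) and filter all voxels with one
# matrix product. The series is extended by symmetric (even) reflection at
# both ends before forward-backward filtering to suppress edge transients,
# then trimmed back; even reflection continues a label/control alternation
# seamlessly, so the perfusion frequency is not distorted at the edges.
filtfilt_operator <- function(order, w, nt) {
  bf <- signal::butter(order, w, type = "high")
  npad <- min(nt - 1, 3 * (order + 1) * 4)
  fop <- matrix(0, nt, nt)
  head_i <- seq(npad + 1, 2)
  tail_i <- seq(nt - 1, nt - npad)
  for (j in seq_len(nt)) {
    e <- numeric(nt); e[j] <- 1
    ep <- c(e[head_i], e, e[tail_i])
    yf <- signal::filtfilt(bf, ep)
    fop[, j] <- yf[seq(npad + 1, npad + nt)]
  }
  fop
}

# --- masking ----------------------------------------------------------------

#' Threshold-based brain mask from the M0 image
#'
#' Voxels above a fraction of the robust (98th percentile) maximum, reduced
#' to the largest 6-connected component. Scale-free by construction.
#'
#' @param m0 3D non-negative M0 volume.
#' @param frac threshold as a fraction of the robust maximum (default 0.3).
#' @return logical 3D array.
#' @export
make_brain_mask <- function(m0, frac = 0.3) {
  stopifnot(is.array(m0), length(dim(m0)) == 3)
  thr <- frac * robust_max(m0)
  mask <- m0 > thr
  if (!any(mask)) stop("brain mask is empty")
  largest_component(mask)
}

# --- nuisance timecourses ---------------------------------------------------

#' Extract global / WM / CSF nuisance timecourses
#'
#' Per-volume means of the non-M0 volumes over the brain mask (global
#' signal) and over high-probability WM and CSF segments.
#'
#' @param series an `asl_series`.
#' @param tissue a `tissue_maps` on the series grid.
#' @param mask logical brain mask.
#' @param prob_threshold tissue probability defining the WM/CSF segments
#'   (default 0.9).
#' @param motion optional n_volumes x 6 motion parameter matrix to carry
#'   along (M0 row dropped).
#' @return object of class `nuisance_set` with elements `motion`, `global`,
#'   `wm`, `csf`.
#' @export
extract_nuisance_timecourses <- function(series, tissue, mask,
                                         prob_threshold = 0.9,
                                         motion = NULL) {
  stopifnot(inherits(series, "asl_series"), inherits(tissue, "tissue_maps"),
            identical(dim(series$data)[1:3], dim(tissue$gm)))
  idx <- which(series$volume_labels != "m0")
  y <- matrix(series$data[, , , idx], ncol = length(idx))
  wm_seg <- tissue$wm > prob_threshold
  csf_seg <- tissue$csf > prob_threshold
  if (!any(mask)) stop("empty segment after thresholding: brain mask")
  if (!any(wm_seg)) stop("empty segment after thresholding: WM")
  if (!any(csf_seg)) stop("empty segment after thresholding: CSF")
  if (!is.null(motion) && nrow(motion) == length(series$volume_labels)) {
    motion <- motion[idx, , drop = FALSE]
  }
  structure(list(motion = motion,
                 global = colMeans(y[as.vector(mask), , drop = FALSE]),
                 wm = colMeans(y[as.vector(wm_seg), , drop = FALSE]),
                 csf = colMeans(y[as.vector(csf_seg), , drop = FALSE])),
            class = "nuisance_set")
}

# --- nuisance regression ----------------------------------------------------

#' Regress nuisance timecourses out of the series
#'
#' Per-voxel ordinary least squares on an intercept, the nuisance
#' regressors (up to 6 motion + global + WM + CSF), and -- when
#' `protect_alternation` is `TRUE` (default) -- a protected +/-1
#' label/control alternation covariate. The fitted nuisance components are
#' subtracted; the intercept and the alternation component are retained.
#' Without protection, global-signal regression would also remove the
#' perfusion signal, which lives at the alternation (Nyquist) frequency.
#' Nuisance columns collinear with the protected set (or with each other)
#' are dropped with a warning.
#'
#' @param series an `asl_series`.
#' @param nuisance a `nuisance_set`.
#' @param protect_alternation logical; include and retain the alternation
#'   covariate.
#' @return an `asl_series` with nuisance removed from the non-M0 volumes.
#' @export
regress_nuisance <- function(series, nuisance, protect_alternation = TRUE) {
  stopifnot(inherits(series, "asl_series"), inherits(nuisance, "nuisance_set"))
  idx <- which(series$volume_labels != "m0")
  nt <- length(idx)
  alt <- ifelse(series$volume_labels[idx] == "control", 1, -1)
  nuis <- cbind(motion = nuisance$motion, global = nuisance$global,
                wm = nuisance$wm, csf = nuisance$csf)
  if (is.null(nuis) || ncol(nuis) == 0) return(series)
  if (nrow(nuis) != nt) stop("regressor length must match non-M0 volume count")
  if (all(abs(nuis) < 1e-12)) return(series)
  prot <- cbind(intercept = rep(1, nt))
  if (protect_alternation) prot <- cbind(prot, alternation = alt)
  if (is.null(colnames(nuis))) colnames(nuis) <- paste0("n", seq_len(ncol(nuis)))
  # orthogonalize nuisance against the protected block so removal cannot
  # touch the protected subspace
  qp <- qr(prot)
  nuis_o <- nuis - qr.fitted(qp, nuis)
  # a column collinear with the protected block leaves only rounding dust,
  # whose *direction* is arbitrary (and typically overlaps the protected
  # subspace once normalized): drop such columns outright
  live <- sqrt(colSums(nuis_o^2)) > 1e-8 * sqrt(colSums(nuis^2))
  live[is.na(live)] <- FALSE
  dropped <- colnames(nuis)[!live]
  nuis_o <- nuis_o[, live, drop = FALSE]
  if (ncol(nuis_o) == 0) {
    if (length(dropped)) {
      warning("dropping collinear nuisance regressor(s): ",
              paste(dropped, collapse = ", "))
    }
    return(series)
  }
  qn <- qr(nuis_o)
  if (qn$rank < ncol(nuis_o)) {
    dropped <- c(dropped,
                 colnames(nuis_o)[qn$pivot[seq(qn$rank + 1, ncol(nuis_o))]])
    nuis_o <- nuis_o[, qn$pivot[seq_len(qn$rank)], drop = FALSE]
    qn <- qr(nuis_o)
  }
  if (length(dropped)) {
    warning("dropping collinear nuisance regressor(s): ",
            paste(dropped, collapse = ", "))
  }
  d <- dim(series$data)
  y <- matrix(series$data[, , , idx], ncol = nt)
  fitted_nuis <- t(qr.fitted(qn, t(y)))
  out <- series
  out$data[, , , idx] <- array(y - fitted_nuis, dim = c(d[1:3], nt))
  out
}

# --- motion correction ------------------------------------------------------

#' Rigid-body motion correction to the M0 reference
#'
#' Estimates six rigid parameters per volume (3 translations mm, 3 rotations
#' deg) by Gauss-Newton least squares on the intensity difference to the M0
#' volume over the brain mask: steepest-descent images are formed from the
#' spatial gradient of the reference, and the linearized parameter update is
#' iterated to sub-voxel convergence (the standard realignment algorithm).
#' Each volume is then resampled with the inverse of its estimated
#' transform. All-zero volumes are flagged and left untouched with zero
#' parameters.
#'
#' @param series an `asl_series`.
#' @param mask optional logical mask; defaults to [make_brain_mask()] of M0.
#' @param maxit Gauss-Newton iteration cap per volume.
#' @param tol convergence tolerance on the parameter update (mm / deg).
#' @return list with `series` (corrected), `motion` (n_volumes x 6 matrix;
#'   the M0 row is zero) and `flagged` (indices of degenerate volumes).
#' @export
motion_correct <- function(series, mask = NULL, maxit = 30, tol = 1e-4) {
  stopifnot(inherits(series, "asl_series"))
  nt <- dim(series$data)[4]
  if (nt < 3) stop("need at least 3 volumes for motion correction")
  ref <- m0_volume(series)
  if (is.null(mask)) mask <- make_brain_mask(ref)
  d <- dim(ref)
  vx <- abs(diag(series$affine)[1:3])
  midx <- which(mask)
  refv <- ref[midx]
  scale2 <- mean(refv^2)
  # spatial gradient of the reference (central differences, per mm)
  grad <- ref_gradient(ref, vx)
  gx <- grad[[1]][midx]; gy <- grad[[2]][midx]; gz <- grad[[3]][midx]
  # mm coordinates of mask voxels relative to the volume center
  ctr_vox <- (d - 1) / 2
  ctr <- as.numeric(series$affine %*% c(ctr_vox, 1))[1:3]
  co <- arrayInd(midx, d) - 1
  mm <- cbind(co, 1) %*% t(series$affine)
  xc <- mm[, 1] - ctr[1]; yc <- mm[, 2] - ctr[2]; zc <- mm[, 3] - ctr[3]
  # steepest-descent images: translations (mm) and rotations (deg) at p = 0
  d2r <- pi / 180
  jac <- cbind(gx, gy, gz,
               d2r * (-gy * zc + gz * yc),
               d2r * (gx * zc - gz * xc),
               d2r * (-gx * yc + gy * xc))
  jtj <- crossprod(jac)
  motion <- matrix(0, nt, 6,
                   dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz")))
  flagged <- integer()
  out <- series
  prev <- rep(0, 6)
  for (v in seq_len(nt)) {
    if (series$volume_labels[v] == "m0") next
    vol <- series$data[, , , v]
    if (all(vol == 0)) {
      flagged <- c(flagged, v)
      prev <- rep(0, 6)
      next
    }
    if (mean((vol[midx] - refv)^2) < 1e-14 * scale2) {
      prev <- rep(0, 6)
      next
    }
    p <- prev
    for (it in seq_len(maxit)) {
      w <- resample_rigid(vol, series$affine, p, invert = TRUE)
      r <- w[midx] - refv
      delta <- tryCatch(solve(jtj, crossprod(jac, r)),
                        error = function(e) rep(0, 6))
      p <- p - as.numeric(delta)
      if (max(abs(delta)) < tol) break
    }
    motion[v, ] <- p
    out$data[, , , v] <- resample_rigid(vol, series$affine, p, invert = TRUE)
    prev <- p
  }
  list(series = out, motion = motion, flagged = flagged)
}

ref_gradient <- function(ref, vx) {
  d <- dim(ref)
  g <- list()
  for (ax in 1:3) {
    plus <- ref; minus <- ref
    n <- d[ax]
    idx_p <- c(2:n, n); idx_m <- c(1, 1:(n - 1))
    if (ax == 1) { plus <- ref[idx_p, , , drop = FALSE]; minus <- ref[idx_m, , , drop = FALSE] }
    if (ax == 2) { plus <- ref[, idx_p, , drop = FALSE]; minus <- ref[, idx_m, , drop = FALSE] }
    if (ax == 3) { plus <- ref[, , idx_p, drop = FALSE]; minus <- ref[, , idx_m, drop = FALSE] }
    g[[ax]] <- array((plus - minus) / (2 * vx[ax]), dim = d)
  }
  g
}

# --- chain ------------------------------------------------------------------

#' Run the full denoising chain
#'
#' Fixed order: motion correction, spatial smoothing, temporal high-pass
#' filtering, nuisance regression. Output grids always equal input grids.
#'
#' @param series an `asl_series`.
#' @param tissue a `tissue_maps` on the series grid.
#' @param fwhm_mm smoothing kernel FWHM (mm).
#' @param cutoff_hz high-pass cutoff (Hz).
#' @param order Butterworth order.
#' @param correct_motion estimate and apply rigid motion correction; when
#'   `FALSE` zero motion parameters are carried forward.
#' @param protect_alternation see [regress_nuisance()].
#' @param mask_frac threshold fraction for [make_brain_mask()].
#' @return list with `series`, `motion`, `nuisance`, `mask`.
#' @export
preprocess_asl <- function(series, tissue, fwhm_mm = 4, cutoff_hz = 0.01,
                           order = 2, correct_motion = TRUE,
                           protect_alternation = TRUE, mask_frac = 0.3) {
  mask <- make_brain_mask(m0_volume(series), frac = mask_frac)
  if (correct_motion) {
    mc <- motion_correct(series, mask = mask)
    series <- mc$series
    motion <- mc$motion
  } else {
    motion <- matrix(0, dim(series$data)[4], 6)
  }
  series <- smooth_gaussian(series, fwhm_mm = fwhm_mm)
  series <- highpass_butterworth(series, cutoff_hz = cutoff_hz, order = order)
  nuis <- extract_nuisance_timecourses(series, tissue, mask, motion = motion)
  series <- regress_nuisance(series, nuis,
                             protect_alternation = protect_alternation)
  list(series = series, motion = motion, nuisance = nuis, mask = mask)
}
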