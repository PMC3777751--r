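# Pairwise subtraction and one-compartment QUIPSS-II PASL CBF quantification.

#' Quantification parameters for the one-compartment PASL model
#'
#' Defaults follow the standard 3T one-compartment QUIPSS-II configuration:
#' bolus duration TI1 = 700 ms, inversion-to-imaging time TI2 = 1900 ms,
#' arterial blood T1 = 1664 ms, labeling efficiency 0.95, blood-brain
#' partition coefficient 0.9 ml/g, and a 45 ms per-slice acquisition delay
#' for the sequential 2D readout. All are overridable; nothing downstream
#' depends on the defaults implicitly.
#'
#' @param ti1_ms bolus duration (ms).
#' @param ti2_ms inversion-to-imaging time of the first slice (ms).
#' @param t1_blood_ms longitudinal relaxation time of arterial blood (ms).
#' @param alpha labeling efficiency in (0, 1].
#' @param lambda blood-brain partition coefficient (ml/g).
#' @param slice_time_ms per-slice acquisition increment (ms); slice k
#'   (0-based) is imaged at TI2 + k * slice_time_ms.
#' @return object of class `quant_params`.
#' @export
quant_params <- function(ti1_ms = 700, ti2_ms = 1900, t1_blood_ms = 1664,
                         alpha = 0.95, lambda = 0.9, slice_time_ms = 45) {
  vals <- c(ti1_ms, ti2_ms, t1_blood_ms, alpha, lambda, slice_time_ms)
  if (any(!is.finite(vals)) || any(vals[-6] <= 0) || slice_time_ms < 0) {
    stop("all quantification parameters must be positive")
  }
  if (alpha > 1) stop("labeling efficiency alpha must lie in (0, 1]")
  if (ti2_ms <= ti1_ms) stop("ti2_ms must exceed ti1_ms")
  structure(list(ti1_ms = ti1_ms, ti2_ms = ti2_ms, t1_blood_ms = t1_blood_ms,
                 alpha = alpha, lambda = lambda, slice_time_ms = slice_time_ms),
            class = "quant_params")
}

#' @export
print.quant_params <- function(x, ...) {
  cat(sprintf(paste0("<quant_params> TI1/TI2 = %g/%g ms, T1blood = %g ms, ",
                     "alpha = %g, lambda = %g ml/g, slice time = %g ms\n"),
              x$ti1_ms, x$ti2_ms, x$t1_blood_ms, x$alpha, x$lambda,
              x$slice_time_ms))
  invisible(x)
}

# CBF [ml/100g/min] = conv_k * dM / M0, per 0-based slice index k:
#   conv_k = 6000 * lambda / (2 * alpha * (TI1/1000) * exp(-TI2_k / T1blood))
# with TI2_k = TI2 + k * slice_time. Shared by quantification and the phantom
# forward model, so the two are exact inverses under any parameter set.
slice_conversion <- function(params, nz) {
  stopifnot(inherits(params, "quant_params"))
  k <- seq_len(nz) - 1
  ti2k <- params$ti2_ms + k * params$slice_time_ms
  6000 * params$lambda /
    (2 * params$alpha * (params$ti1_ms / 1000) * exp(-ti2k / params$t1_blood_ms))
}

#' Pairwise control-minus-label subtraction
#'
#' One difference map per adjacent (label, control) pair, always computed as
#' control minus label regardless of acquisition order. No interleaved or
#' surround subtraction is performed.
#'
#' @param series an `asl_series` with valid alternation tags.
#' @return object of class `dm_stack`: list with `dm` (4D array, one volume
#'   per pair) and `pair_index` (2-column matrix of source volume indices,
#'   label then control).
#' @export
pairwise_subtract <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  labs <- series$volume_labels
  validate_volume_labels(labs, length(labs))
  idx <- which(labs != "m0")
  if (length(idx) %% 2 != 0) stop("odd number of non-M0 volumes")
  n_pairs <- length(idx) / 2
  d <- dim(series$data)[1:3]
  dm <- array(0, dim = c(d, n_pairs))
  pair_index <- matrix(0L, n_pairs, 2,
                       dimnames = list(NULL, c("label", "control")))
  for (p in seq_len(n_pairs)) {
    v1 <- idx[2 * p - 1]; v2 <- idx[2 * p]
    if (labs[v1] == "label") {
      lab_i <- v1; con_i <- v2
    } else {
      lab_i <- v2; con_i <- v1
    }
    dm[, , , p] <- series$data[, , , con_i] - series$data[, , , lab_i]
    pair_index[p, ] <- c(lab_i, con_i)
  }
  structure(list(dm = dm, pair_index = pair_index, affine = series$affine),
            class = "dm_stack")
}

#' Quantify CBF from a difference-map stack
#'
#' One-compartment QUIPSS-II model with slice-dependent inversion time for a
#' sequential ascending 2D readout. Voxels whose M0 falls below
#' `m0_floor_frac` of the robust (98th percentile) maximum are set to 0 and
#' flagged in the `m0_valid` attribute; negative CBF values are retained for
#' downstream quality control.
#'
#' @param dm a `dm_stack` from [pairwise_subtract()] (or a 4D array).
#' @param m0 3D M0 calibration volume.
#' @param params a `quant_params` object.
#' @param m0_floor_frac fraction of the robust M0 maximum below which voxels
#'   are excluded from quantification.
#' @return object of class `cbf_series`: `maps` (4D, ml/100 g/min),
#'   `pair_index`, `kept` (logical per map, initially all `TRUE`) and
#'   `m0_valid` (logical 3D array).
#' @export
quantify_cbf <- function(dm, m0, params = quant_params(), m0_floor_frac = 0.1) {
  stopifnot(inherits(params, "quant_params"))
  pair_index <- NULL
  affine <- NULL
  if (inherits(dm, "dm_stack")) {
    pair_index <- dm$pair_index
    affine <- dm$affine
    dm <- dm$dm
  }
  stopifnot(is.array(dm), length(dim(dm)) == 4,
            identical(dim(dm)[1:3], dim(m0)))
  d <- dim(dm)
  valid <- m0 >= m0_floor_frac * robust_max(m0) & m0 > 0
  conv <- slice_conversion(params, d[3])
  conv_vol <- aperm(array(conv, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  scale <- array(0, dim = d[1:3])
  scale[valid] <- conv_vol[valid] / m0[valid]
  maps <- array(as.numeric(dm) * as.numeric(scale), dim = d)
  structure(list(maps = maps, pair_index = pair_index, affine = affine,
                 kept = rep(TRUE, d[4]), m0_valid = valid),
            class = "cbf_series")
}

#' @export
print.cbf_series <- function(x, ...) {
  d <- dim(x$maps)
  cat(sprintf("<cbf_series> %d maps (%d kept) on %dx%dx%d grid\n",
              d[4], sum(x$kept), d[1], d[2], d[3]))
  invisible(x)
}

# Inverse of quantify_cbf used by the phantom forward model:
# dM = CBF * M0 / conv_k
delta_m_from_cbf <- function(cbf_map, m0, params) {
  d <- dim(cbf_map)
  conv <- slice_conversion(params, d[3])
  conv_vol <- aperm(array(conv, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  cbf_map * m0 / conv_vol
}
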