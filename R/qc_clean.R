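# Adaptive cleaning of the CBF time series and subject-level QC.

#' Initial outlier screening from motion and whole-brain CBF
#'
#' Flags CBF maps (label/control pairs) whose framewise displacement exceeds
#' `fd_mm`, or whose whole-brain mean CBF lies outside mean +/- `k_sd`
#' standard deviations of the series. Framewise displacement is computed per
#' volume as the sum of absolute translation increments plus 50 mm times the
#' absolute rotation increments in radians; each pair inherits the maximum
#' over its two volumes.
#'
#' @param motion matrix of 6 rigid parameters for the non-M0 volumes (two
#'   rows per pair, in acquisition order).
#' @param wholebrain_cbf numeric vector, mean CBF over the brain mask per map.
#' @param fd_mm framewise displacement threshold (default 1.5 mm).
#' @param k_sd whole-brain CBF z-score band (default 2.5).
#' @return sorted integer vector of flagged map indices.
#' @export
initial_outliers <- function(motion, wholebrain_cbf, fd_mm = 1.5, k_sd = 2.5) {
  n_maps <- length(wholebrain_cbf)
  if (n_maps < 4) stop("need at least 4 CBF maps for stable screening")
  stopifnot(is.matrix(motion), ncol(motion) == 6,
            nrow(motion) == 2 * n_maps)
  dt <- rbind(0, abs(diff(motion[, 1:3, drop = FALSE])))
  dr <- rbind(0, abs(diff(motion[, 4:6, drop = FALSE] * pi / 180)))
  fd <- rowSums(dt) + 50 * rowSums(dr)
  fd_pair <- pmax(fd[seq(1, 2 * n_maps, by = 2)], fd[seq(2, 2 * n_maps, by = 2)])
  wb_z <- abs(wholebrain_cbf - mean(wholebrain_cbf))
  s <- stats::sd(wholebrain_cbf)
  flagged <- fd_pair > fd_mm | (s > 0 & wb_z > k_sd * s)
  sort(which(flagged))
}

#' Adaptive correlation-based cleaning of the CBF time series
#'
#' Iteratively removes CBF maps that do not resemble the rest of the series
#' over gray matter. At each iteration the Pearson correlation (CC) between
#' the GM voxels of each map and the voxelwise mean of the remaining kept
#' maps (leave-one-out) is computed; maps with CC below `cc_floor` (default
#' 0.15) or outside mean +/- `k_sd` SD of the image CCs are removed, and the
#' iteration repeats until no new outlier is found.
#'
#' By default the CC mean/SD band is computed over all maps' CCs, including
#' already-removed ones ("all image CCs"): outlying maps then keep the band
#' wide, which is what lets the procedure converge in one or two iterations
#' instead of repeatedly trimming the tails of an ever-tighter CC
#' distribution. `band_scope = "kept"` restricts the band to currently kept
#' maps. When the kept-map CCs are numerically degenerate (SD below 1e-8,
#' e.g. identical maps) the band rule is inactive.
#'
#' @param cbf a `cbf_series`.
#' @param gm_mask logical gray-matter mask (nonempty).
#' @param cc_floor absolute correlation floor (default 0.15).
#' @param k_sd width of the CC band in standard deviations (default 2).
#' @param include_self include map i itself in the reference mean (default
#'   `FALSE`, i.e. leave-one-out).
#' @param band_scope `"all"` (default) or `"kept"`; see Details.
#' @param initial map indices already flagged by [initial_outliers()]; they
#'   never contribute to reference means.
#' @return list with `cbf` (kept flags updated) and `report` (a
#'   `qc_report`: initial and per-iteration adaptive outlier indices, final
#'   per-map CCs, iteration count, totals, and the thresholds used).
#' @export
adaptive_clean <- function(cbf, gm_mask, cc_floor = 0.15, k_sd = 2,
                           include_self = FALSE,
                           band_scope = c("all", "kept"),
                           initial = integer()) {
  band_scope <- match.arg(band_scope)
  stopifnot(inherits(cbf, "cbf_series"))
  n_maps <- dim(cbf$maps)[4]
  if (!any(gm_mask)) stop("gray-matter mask is empty")
  g <- matrix(cbf$maps, ncol = n_maps)[as.vector(gm_mask), , drop = FALSE]
  kept <- cbf$kept
  kept[initial] <- FALSE
  if (sum(kept) < 4) stop("need at least 4 kept CBF maps")
  adaptive <- list()
  cc <- rep(NA_real_, n_maps)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    kidx <- which(kept)
    tot <- rowSums(g[, kidx, drop = FALSE])
    nk <- length(kidx)
    for (i in seq_len(n_maps)) {
      if (kept[i] && !include_self) {
        ref <- (tot - g[, i]) / (nk - 1)
      } else {
        ref <- tot / nk
      }
      cc[i] <- stats::cor(g[, i], ref)
    }
    band_cc <- if (band_scope == "all") cc else cc[kept]
    m <- mean(band_cc)
    s <- stats::sd(band_cc)
    low <- cc < cc_floor
    out_band <- if (is.finite(s) && s > 1e-8) abs(cc - m) > k_sd * s else FALSE
    new_out <- which(kept & (low | out_band))
    if (length(new_out) == 0) break
    adaptive[[iter]] <- new_out
    kept[new_out] <- FALSE
    if (!any(kept)) stop("no usable CBF time points remain")
  }
  cbf$kept <- kept
  report <- structure(
    list(initial_outliers = sort(as.integer(initial)),
         adaptive_outliers = adaptive,
         cc_per_map = cc,
         n_iterations = iter,
         n_removed_total = length(initial) + length(unlist(adaptive)),
         coverage_ok = NA, negativity_ok = NA,
         params = list(cc_floor = cc_floor, k_sd = k_sd,
                       include_self = include_self,
                       band_scope = band_scope)),
    class = "qc_report")
  list(cbf = cbf, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d removed (%d initial + %d adaptive) in %d iteration(s)\n",
              x$n_removed_total, length(x$initial_outliers),
              length(unlist(x$adaptive_outliers)), x$n_iterations))
  cat(sprintf("  CC floor %g, band %g SD (%s); coverage_ok=%s negativity_ok=%s\n",
              x$params$cc_floor, x$params$k_sd, x$params$band_scope,
              x$coverage_ok, x$negativity_ok))
  invisible(x)
}

#' Average the kept CBF maps into the final CBF image
#'
#' @param cbf a `cbf_series` with at least one kept map.
#' @return 3D array, voxelwise arithmetic mean over kept maps
#'   (ml/100 g/min).
#' @export
finalize_cbf <- function(cbf) {
  stopifnot(inherits(cbf, "cbf_series"))
  kidx <- which(cbf$kept)
  if (length(kidx) == 0) stop("no kept CBF maps to average")
  d <- dim(cbf$maps)
  m <- matrix(cbf$maps, ncol = d[4])[, kidx, drop = FALSE]
  array(rowMeans(m), dim = d[1:3])
}

#' Subject-level quality flags: brain coverage and GM negativity
#'
#' `coverage_ok` requires that at least `coverage_frac` of brain-mask voxels
#' carry nonzero signal in every non-M0 volume (scans that miss part of the
#' brain fail). `negativity_ok` requires that at most `negativity_frac` of
#' gray-matter voxels have negative final CBF (extensive non-physiological
#' negative CBF fails).
#'
#' @param series the `asl_series` (post-acquisition, any preprocessing
#'   stage).
#' @param final_map final mean CBF map from [finalize_cbf()].
#' @param gm_mask logical gray-matter mask.
#' @param mask logical brain mask.
#' @param coverage_frac minimum always-covered fraction (default 0.9).
#' @param negativity_frac maximum negative-GM fraction (default 0.1).
#' @return list with logical `coverage_ok` and `negativity_ok`.
#' @export
subject_qc <- function(series, final_map, gm_mask, mask,
                       coverage_frac = 0.9, negativity_frac = 0.1) {
  stopifnot(inherits(series, "asl_series"))
  idx <- which(series$volume_labels != "m0")
  y <- matrix(series$data[, , , idx], ncol = length(idx))[as.vector(mask), ,
                                                          drop = FALSE]
  covered <- rowSums(y != 0) == ncol(y)
  coverage_ok <- mean(covered) >= coverage_frac
  neg_frac <- mean(final_map[gm_mask] < 0)
  list(coverage_ok = coverage_ok, negativity_ok = neg_frac <= negativity_frac)
}
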