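# Digital perfusion phantom: tissue geometry, forward PASL signal model,
# and cohort generation with group-graded CBF / hippocampal effects.

#' Specification of a single-subject digital PASL phantom
#'
#' Defaults reproduce the acquisition geometry of the multi-site pulsed-ASL
#' protocol this pipeline targets: 64 x 64 in-plane matrix, 24 slices of
#' 4 mm with a 25% gap (5 mm pitch), TR 3400 ms, TI1/TI2 = 700/1900 ms, 105
#' volumes (1 M0 + 52 label/control pairs). Noise and drift magnitudes are
#' simulation assumptions, not protocol values; see the package vignette.
#'
#' @param grid_shape integer length-3 voxel counts.
#' @param voxel_size mm per voxel; the third element is the slice pitch
#'   (slice thickness plus gap).
#' @param n_volumes total volumes including the leading M0; must be odd.
#' @param tr_ms,ti1_ms,ti2_ms sequence timing (ms).
#' @param gm_cbf_true,wm_cbf_true ground-truth perfusion of pure gray and
#'   white matter (ml/100 g/min).
#' @param noise_sd thermal noise standard deviation (scanner units).
#' @param drift_amplitude amplitude of a slow sinusoidal global signal drift
#'   (scanner units); `drift_period_s` sets its period.
#' @param drift_period_s drift period in seconds.
#' @param pd_gm,pd_wm,pd_csf proton-density (M0) signal of pure tissue, in
#'   scanner units.
#' @param motion_schedule optional `n_volumes` x 6 matrix of rigid-body
#'   motion per volume (3 translations mm, 3 rotations deg) applied in the
#'   forward model.
#' @param outlier_schedule optional data frame with columns `volume`
#'   (index in 2..n_volumes) and `type` (`"noise"` for a spatially
#'   decorrelated noise burst, which decorrelates the affected difference
#'   map; `"offset"` for a global intensity jump, which shifts the
#'   whole-brain CBF level of the affected pair).
#' @param outlier_noise_frac burst standard deviation of a `"noise"`
#'   corruption, as a fraction of mean brain signal (default 0.015).
#' @param outlier_offset_frac intensity jump of an `"offset"` corruption,
#'   as a fraction of mean brain signal (default 0.05).
#' @param first_volume whether the label or the control member of each pair
#'   is acquired first.
#' @param seed integer RNG seed; the simulation is bit-reproducible given
#'   the spec.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 24),
                         voxel_size = c(3.4, 3.4, 5.0),
                         n_volumes = 105, tr_ms = 3400,
                         ti1_ms = 700, ti2_ms = 1900,
                         gm_cbf_true = 55, wm_cbf_true = 20,
                         noise_sd = 0.75,
                         drift_amplitude = 5, drift_period_s = 200,
                         pd_gm = 850, pd_wm = 700, pd_csf = 1000,
                         motion_schedule = NULL, outlier_schedule = NULL,
                         outlier_noise_frac = 0.015,
                         outlier_offset_frac = 0.05,
                         first_volume = c("label", "control"),
                         seed = 1L) {
  first_volume <- match.arg(first_volume)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(voxel_size) == 3, all(voxel_size > 0),
            n_volumes >= 3, (n_volumes - 1) %% 2 == 0,
            tr_ms > 0, ti1_ms > 0, ti2_ms > ti1_ms,
            gm_cbf_true >= 0, wm_cbf_true >= 0, noise_sd >= 0,
            drift_amplitude >= 0, drift_period_s > 0)
  if (!is.null(motion_schedule)) {
    stopifnot(is.matrix(motion_schedule),
              nrow(motion_schedule) == n_volumes,
              ncol(motion_schedule) == 6)
  }
  if (!is.null(outlier_schedule)) {
    stopifnot(is.data.frame(outlier_schedule),
              all(c("volume", "type") %in% names(outlier_schedule)),
              all(outlier_schedule$volume >= 2),
              all(outlier_schedule$volume <= n_volumes),
              all(outlier_schedule$type %in% c("noise", "offset")))
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_volumes = as.integer(n_volumes),
                 tr_ms = tr_ms, ti1_ms = ti1_ms, ti2_ms = ti2_ms,
                 gm_cbf_true = gm_cbf_true, wm_cbf_true = wm_cbf_true,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 pd_gm = pd_gm, pd_wm = pd_wm, pd_csf = pd_csf,
                 motion_schedule = motion_schedule,
                 outlier_schedule = outlier_schedule,
                 outlier_noise_frac = outlier_noise_frac,
                 outlier_offset_frac = outlier_offset_frac,
                 first_volume = first_volume, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build concentric-shell tissue maps and the ground-truth CBF map
#'
#' A simple brain-like geometry: an ellipsoidal CSF core ("ventricles"), a
#' white-matter shell, and an outer gray-matter shell, with probabilities
#' softened by a small Gaussian so that boundary voxels carry genuine
#' partial-volume mixtures. The ground-truth perfusion map is
#' `gm_cbf_true * P_GM + wm_cbf_true * P_WM`.
#'
#' @param spec a `phantom_spec`.
#' @return list with elements `tissue` (a [tissue_maps()] object) and
#'   `cbf_true` (3D array, ml/100 g/min).
#' @export
make_tissue_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  vx <- spec$voxel_size
  affine <- voxel_affine(vx)
  ctr <- (d - 1) / 2 * vx
  # brain ellipsoid semi-axes, mm; in-plane anisotropy mimics the
  # anterior-posterior elongation of a head and makes in-plane rotation
  # identifiable for motion estimation
  semi <- c(0.40, 0.46, 0.44) * d * vx
  mm <- voxel_centers_mm(d, affine)
  rho <- sqrt(((mm[, 1] - ctr[1]) / semi[1])^2 +
              ((mm[, 2] - ctr[2]) / semi[2])^2 +
              ((mm[, 3] - ctr[3]) / semi[3])^2)
  rho <- array(rho, dim = d)
  csf <- (rho < 0.35) * 1.0
  wm  <- (rho >= 0.35 & rho < 0.62) * 1.0
  gm  <- (rho >= 0.62 & rho < 0.95) * 1.0
  sig <- 0.6                                 # voxels; soft partial-volume edges
  csf <- gauss_smooth_volume(csf, rep(sig, 3))
  wm  <- gauss_smooth_volume(wm, rep(sig, 3))
  gm  <- gauss_smooth_volume(gm, rep(sig, 3))
  tot <- csf + wm + gm
  over <- tot > 1
  if (any(over)) {
    csf[over] <- csf[over] / tot[over]
    wm[over] <- wm[over] / tot[over]
    gm[over] <- gm[over] / tot[over]
  }
  if (sum(gm > 0.5) == 0 || sum(wm > 0.5) == 0 || sum(csf > 0.5) == 0) {
    stop("grid too small to contain CSF core, WM shell and GM shell")
  }
  tissue <- tissue_maps(gm, wm, csf, affine)
  cbf_true <- spec$gm_cbf_true * gm + spec$wm_cbf_true * wm
  list(tissue = tissue, cbf_true = cbf_true)
}

#' Assemble a ground-truth record for a phantom subject
#'
#' @param cbf_map ground-truth CBF map (ml/100 g/min, non-negative).
#' @param tissue a `tissue_maps` object on the same grid.
#' @param outlier_indices volume indices (2..n_volumes) of corrupted volumes.
#' @param motion applied motion schedule (n_volumes x 6) or `NULL`.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(cbf_map, tissue, outlier_indices = integer(),
                         motion = NULL) {
  stopifnot(inherits(tissue, "tissue_maps"),
            identical(dim(cbf_map), dim(tissue$gm)))
  if (any(cbf_map < 0)) stop("ground-truth CBF must be non-negative")
  structure(list(cbf_map = cbf_map, tissue = tissue,
                 outlier_indices = as.integer(outlier_indices),
                 motion = motion),
            class = "ground_truth")
}

#' Simulate a 4D PASL acquisition from ground truth
#'
#' The forward model inverts the one-compartment quantification exactly: at
#' every voxel the noiseless control-minus-label difference equals the
#' `delta M` implied by the ground-truth CBF, the M0 (proton-density) map
#' and the same `quant_params` object used for quantification, so that a
#' noise-free round trip recovers the truth to machine precision. Thermal
#' noise, slow global drift, rigid motion and scheduled volume corruptions
#' are then layered on top.
#'
#' @param spec a `phantom_spec`.
#' @param truth a `ground_truth` on the same grid.
#' @param params a `quant_params`; defaults to the spec's timing.
#' @return an `asl_series`.
#' @export
simulate_subject_series <- function(spec, truth,
                                    params = quant_params(ti1_ms = spec$ti1_ms,
                                                          ti2_ms = spec$ti2_ms)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "ground_truth"))
  d <- spec$grid_shape
  if (!identical(dim(truth$cbf_map), d)) {
    stop("ground-truth grid does not match the phantom spec grid")
  }
  set.seed(spec$seed)
  affine <- voxel_affine(spec$voxel_size)
  ts <- truth$tissue
  pd <- spec$pd_gm * ts$gm + spec$pd_wm * ts$wm + spec$pd_csf * ts$csf
  dm <- delta_m_from_cbf(truth$cbf_map, pd, params)
  nt <- spec$n_volumes
  labels <- make_volume_labels(nt, spec$first_volume)
  nv <- prod(d)
  data <- array(0, dim = c(d, nt))
  phase <- stats::runif(1, 0, 2 * pi)
  tsec <- (seq_len(nt) - 1) * spec$tr_ms / 1000
  drift <- spec$drift_amplitude * sin(2 * pi * tsec / spec$drift_period_s + phase)
  brain <- pd > 0.05 * max(pd)
  for (v in seq_len(nt)) {
    base <- switch(labels[v], m0 = pd, control = pd, label = pd - dm)
    vol <- base
    if (labels[v] != "m0") vol <- vol + drift[v] * brain
    if (spec$noise_sd > 0) vol <- vol + stats::rnorm(nv, sd = spec$noise_sd)
    data[, , , v] <- vol
  }
  if (!is.null(spec$outlier_schedule)) {
    m_brain <- mean(pd[brain])
    for (r in seq_len(nrow(spec$outlier_schedule))) {
      v <- spec$outlier_schedule$volume[r]
      if (spec$outlier_schedule$type[r] == "noise") {
        # spatially decorrelated noise burst at tissue-contrast magnitude;
        # added on top of the anatomy so the corrupted pair difference is
        # decorrelated noise, not an anatomical residual
        data[, , , v] <- data[, , , v] +
          stats::rnorm(nv, sd = spec$outlier_noise_frac * m_brain)
      } else {
        data[, , , v] <- data[, , , v] + spec$outlier_offset_frac * m_brain * brain
      }
    }
  }
  if (!is.null(spec$motion_schedule)) {
    for (v in seq_len(nt)) {
      p <- spec$motion_schedule[v, ]
      if (any(p != 0)) {
        data[, , , v] <- resample_rigid(data[, , , v], affine, p)
      }
    }
  }
  asl_series(data, affine = affine, volume_labels = labels,
             tr_ms = spec$tr_ms)
}

# map scheduled corrupted volume indices (2..n_volumes) to pair indices
outlier_pair_indices <- function(spec) {
  if (is.null(spec$outlier_schedule)) return(integer())
  sort(unique((spec$outlier_schedule$volume - 2L) %/% 2L + 1L))
}

#' Specification of a synthetic study cohort
#'
#' Group structure mirrors a four-stage prodromal-AD design (CN, early MCI,
#' late MCI, AD). Default group sizes are the analyzed sample of the target
#' protocol, n = (44, 31, 30, 15); demographic means/SDs follow its
#' demographic table, and the graded meta-ROI CBF decline and hippocampal
#' atrophy follow the reported standardized effect sizes (CBF deficits of
#' about 0.27/0.58/1.09 pooled SD for EMCI/LMCI/AD, hippocampal effects of
#' about -0.35/0.26/1.30); the CBF spacing is set on the measured scale
#' (true SD combined with measurement noise), since reported effect sizes
#' are always on measured values. Severity scores are generated as noisy linear
#' functions of the true biomarkers, so that both carry independent signal.
#'
#' @param n_per_group named or ordered integer vector for CN, EMCI, LMCI, AD.
#' @param group_cbf_means,group_cbf_sds true meta-ROI CBF distribution per
#'   group (ml/100 g/min).
#' @param group_hippo_means,group_hippo_sds mean bilateral hippocampal
#'   volume per group (mm^3, average of left and right).
#' @param age_means,age_sds,education_means,education_sds demographics per
#'   group (years).
#' @param female_prob probability of female sex per group.
#' @param icv_mean,icv_sd intracranial volume (GM+WM+CSF, mm^3).
#' @param cbf_meas_sd measurement noise added to true meta-ROI CBF to form
#'   the measured value (ml/100 g/min).
#' @param control_cbf_mean,control_cbf_sd control-ROI (visual cortex) CBF,
#'   identical across groups by construction.
#' @param cdr_sb_model,mmse_model,wms_model lists with `intercept`, `b_cbf`
#'   (per ml/100 g/min), `b_hippo` (per mm^3) and `sd` defining the linear
#'   severity maps.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CN = 44, EMCI = 31, LMCI = 30, AD = 15),
                        group_cbf_means = c(50, 47.7, 45.1, 40.9),
                        group_cbf_sds = rep(8, 4),
                        group_hippo_means = c(3700, 3858, 3583, 3115),
                        group_hippo_sds = rep(450, 4),
                        age_means = c(73.0, 68.7, 72.3, 75.6),
                        age_sds = c(7.0, 7.2, 7.4, 8.8),
                        education_means = c(16.3, 16.6, 16.6, 15.7),
                        education_sds = c(2.5, 2.8, 2.9, 2.8),
                        female_prob = c(26 / 44, 14 / 31, 14 / 30, 4 / 15),
                        icv_mean = 1.45e6, icv_sd = 1.2e5,
                        cbf_meas_sd = 2.5,
                        control_cbf_mean = 48, control_cbf_sd = 6,
                        cdr_sb_model = list(intercept = 1.5, b_cbf = -0.12,
                                            b_hippo = -0.002, sd = 1.8),
                        mmse_model = list(intercept = 27.5, b_cbf = 0.10,
                                          b_hippo = 0.0015, sd = 1.5),
                        wms_model = list(intercept = 8, b_cbf = 0.16,
                                         b_hippo = 0.003, sd = 2.8),
                        seed = 1L) {
  stopifnot(length(n_per_group) == 4)
  if (any(n_per_group < 2)) stop("every group needs at least 2 subjects")
  stopifnot(all(group_cbf_sds > 0), all(group_hippo_sds > 0),
            all(age_sds > 0), all(education_sds > 0),
            icv_sd > 0, cbf_meas_sd >= 0, control_cbf_sd > 0)
  for (m in list(cdr_sb_model, mmse_model, wms_model)) {
    stopifnot(all(c("intercept", "b_cbf", "b_hippo", "sd") %in% names(m)),
              m$sd >= 0)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 group_cbf_means = group_cbf_means,
                 group_cbf_sds = group_cbf_sds,
                 group_hippo_means = group_hippo_means,
                 group_hippo_sds = group_hippo_sds,
                 age_means = age_means, age_sds = age_sds,
                 education_means = education_means,
                 education_sds = education_sds,
                 female_prob = female_prob,
                 icv_mean = icv_mean, icv_sd = icv_sd,
                 cbf_meas_sd = cbf_meas_sd,
                 control_cbf_mean = control_cbf_mean,
                 control_cbf_sd = control_cbf_sd,
                 cdr_sb_model = cdr_sb_model, mmse_model = mmse_model,
                 wms_model = wms_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort covariate / biomarker table
#'
#' Draws one record per subject: demographics, true and measured meta-ROI
#' CBF, a group-independent control-ROI CBF, hippocampal volume, ICV and
#' severity scores generated from the linear severity models. The control
#' ROI carries no group effect by construction, mirroring the regional
#' specificity control of the analysis.
#'
#' @param cspec a `cohort_spec`.
#' @return a `data.frame` of class `cohort_table`, one row per subject.
#' @export
simulate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  if (any(cspec$n_per_group < 2)) stop("every group needs at least 2 subjects")
  set.seed(cspec$seed)
  groups <- c("CN", "EMCI", "LMCI", "AD")
  rows <- vector("list", 4)
  cbf_ref <- stats::weighted.mean(cspec$group_cbf_means, cspec$n_per_group)
  hip_ref <- stats::weighted.mean(cspec$group_hippo_means, cspec$n_per_group)
  sev <- function(model, n, cbf, hip) {
    model$intercept + model$b_cbf * (cbf - cbf_ref) +
      model$b_hippo * (hip - hip_ref) + stats::rnorm(n, sd = model$sd)
  }
  for (g in 1:4) {
    n <- cspec$n_per_group[g]
    cbf_true <- stats::rnorm(n, cspec$group_cbf_means[g], cspec$group_cbf_sds[g])
    hippo <- stats::rnorm(n, cspec$group_hippo_means[g], cspec$group_hippo_sds[g])
    hippo <- pmax(hippo, 500)
    icv <- pmax(stats::rnorm(n, cspec$icv_mean, cspec$icv_sd), 8e5)
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s%03d", groups[g], seq_len(n)),
      group = groups[g],
      age = stats::rnorm(n, cspec$age_means[g], cspec$age_sds[g]),
      education = pmax(stats::rnorm(n, cspec$education_means[g],
                                    cspec$education_sds[g]), 6),
      sex = ifelse(stats::runif(n) < cspec$female_prob[g], "F", "M"),
      meta_roi_cbf_true = cbf_true,
      meta_roi_cbf = cbf_true + stats::rnorm(n, sd = cspec$cbf_meas_sd),
      control_roi_cbf = stats::rnorm(n, cspec$control_cbf_mean,
                                     cspec$control_cbf_sd) +
        stats::rnorm(n, sd = cspec$cbf_meas_sd),
      hippo_volume = hippo,
      icv = icv,
      hippo_norm = hippo / icv,
      cdr_sb = pmax(sev(cspec$cdr_sb_model, n, cbf_true, hippo), 0),
      mmse = pmin(pmax(sev(cspec$mmse_model, n, cbf_true, hippo), 0), 30),
      wms_lm_delayed = pmax(sev(cspec$wms_model, n, cbf_true, hippo), 0),
      qc_pass = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = groups)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
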