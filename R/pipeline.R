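# End-to-end orchestration: simulate -> preprocess -> quantify -> clean ->
# PVC/ROI -> group statistics, with per-subject artifacts and a manifest.

#' Phantom-space spherical ROI definitions
#'
#' Places a three-sphere disease-tracking composite ("meta") ROI and a
#' single-sphere control ROI inside the gray-matter shell of the phantom
#' geometry, at the mid-slice plane. Positions are derived from the spec's
#' grid, never hard-coded in mm.
#'
#' @param spec a `phantom_spec`.
#' @param radius_mm sphere radius (default 8 mm).
#' @return list with `roi_spec` elements `meta` and `control`.
#' @export
phantom_roi_specs <- function(spec, radius_mm = 8) {
  d <- spec$grid_shape; vx <- spec$voxel_size
  ctr <- (d - 1) / 2 * vx
  semi <- 0.44 * d * vx
  r_gm <- 0.785 * min(semi[1:2])      # mid-GM-shell radius in-plane
  at <- function(az_deg) {
    c(ctr[1] + r_gm * cos(az_deg * pi / 180),
      ctr[2] + r_gm * sin(az_deg * pi / 180), ctr[3])
  }
  list(meta = roi_spec("meta", rbind(at(90), at(30), at(150)),
                       radius_mm, role = "meta"),
       control = roi_spec("control", rbind(at(270)), radius_mm,
                          role = "control"))
}

#' Assemble a pipeline configuration
#'
#' @param cohort a `cohort_spec`.
#' @param phantom a `phantom_spec` used as the per-subject template (its
#'   seed and outlier schedule are replaced per subject).
#' @param quant a `quant_params`.
#' @param fwhm_mm,cutoff_hz,correct_motion,protect_alternation preprocessing
#'   options (see [preprocess_asl()]).
#' @param fd_mm,k_sd_initial initial screening thresholds
#'   (see [initial_outliers()]).
#' @param cc_floor,k_sd_cc adaptive cleaning thresholds
#'   (see [adaptive_clean()]).
#' @param coverage_frac,negativity_frac subject QC thresholds
#'   (see [subject_qc()]).
#' @param wm_ratio,gm_floor PVE correction parameters.
#' @param roi_radius_mm sphere radius for the phantom-space ROIs.
#' @param n_outlier_volumes corrupted volumes injected per subject.
#' @param simulate_images run the full image pipeline per subject; when
#'   `FALSE` the cohort table's statistically simulated biomarkers are used
#'   directly (table-level run).
#' @param seed master RNG seed; per-subject seeds are derived from it.
#' @param out_dir output directory (`NULL` for no artifacts).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            phantom = phantom_spec(),
                            quant = quant_params(ti1_ms = phantom$ti1_ms,
                                                 ti2_ms = phantom$ti2_ms),
                            fwhm_mm = 4, cutoff_hz = 0.01,
                            correct_motion = TRUE,
                            protect_alternation = TRUE,
                            fd_mm = 1.5, k_sd_initial = 2.5,
                            cc_floor = 0.15, k_sd_cc = 2,
                            coverage_frac = 0.9, negativity_frac = 0.1,
                            wm_ratio = 0.4, gm_floor = 0.3,
                            roi_radius_mm = 8,
                            n_outlier_volumes = 3,
                            simulate_images = TRUE,
                            seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(phantom, "phantom_spec"),
            inherits(quant, "quant_params"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulates the cohort table, then (unless `simulate_images = FALSE`) runs
#' each subject through the imaging chain: phantom simulation with the
#' subject's meta-ROI perfusion level, denoising, pairwise subtraction and
#' CBF quantification, initial and adaptive outlier cleaning, averaging,
#' subject QC, partial-volume correction and ROI extraction. Subjects
#' failing QC are excluded from the statistics with reasons recorded.
#' Finally runs the group statistics battery (group models for the meta
#' ROI, control ROI and normalized hippocampal volume; severity partial
#' correlations; hierarchical stepwise regression).
#'
#' @param config a `pipeline_config`.
#' @return list with `cohort` (per-subject table incl. QC outcomes),
#'   `stats`, `qc_reports`, and `manifest`; artifacts are written under
#'   `config$out_dir` if set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  cohort_sp <- config$cohort
  cohort_sp$seed <- config$seed
  cohort <- simulate_cohort(cohort_sp)
  qc_reports <- list()
  log_lines <- character()
  if (config$simulate_images) {
    ph <- config$phantom
    base <- make_tissue_phantom(ph)
    rois <- phantom_roi_specs(ph, config$roi_radius_mm)
    d <- ph$grid_shape
    affine <- base$tissue$affine
    meta_mask <- sphere_mask(rois$meta, d, affine)
    ctrl_mask <- sphere_mask(rois$control, d, affine)
    gm_mask <- tissue_mask(base$tissue, "gm", 0.3)
    set.seed(config$seed)
    subj_seeds <- sample.int(2^30, nrow(cohort))
    cohort$qc_reason <- ""
    cohort$n_removed <- NA_integer_
    for (i in seq_len(nrow(cohort))) {
      res <- tryCatch(
        process_one_subject(cohort[i, ], ph, base, config, subj_seeds[i],
                            meta_mask, ctrl_mask, gm_mask),
        error = function(e) e)
      if (inherits(res, "error")) {
        cohort$qc_pass[i] <- FALSE
        cohort$qc_reason[i] <- conditionMessage(res)
        next
      }
      cohort$meta_roi_cbf[i] <- res$meta_cbf
      cohort$control_roi_cbf[i] <- res$control_cbf
      cohort$qc_pass[i] <- res$qc_pass
      cohort$qc_reason[i] <- res$qc_reason
      cohort$n_removed[i] <- res$report$n_removed_total
      qc_reports[[cohort$subject_id[i]]] <- res$report
      rm_idx <- c(res$report$initial_outliers,
                  unlist(res$report$adaptive_outliers))
      for (j in rm_idx) {
        log_lines <- c(log_lines,
                       sprintf("%s removed map %d CC=%.4f",
                               cohort$subject_id[i], j,
                               res$report$cc_per_map[j]))
      }
      if (!is.null(out_dir)) {
        jsonlite::write_json(
          res$report[c("initial_outliers", "n_iterations",
                       "n_removed_total", "cc_per_map", "params")],
          file.path(out_dir, paste0(cohort$subject_id[i], "_qc.json")),
          auto_unbox = TRUE, digits = NA)
      }
    }
  }
  used <- cohort[cohort$qc_pass, ]
  if (length(unique(used$group)) < 2) {
    stop("fewer than 2 groups survived QC; aborting statistics")
  }
  stats_res <- list(
    meta = group_model(used$meta_roi_cbf, used$group, used$age),
    control = group_model(used$control_roi_cbf, used$group, used$age),
    hippo = group_model(used$hippo_norm, used$group, used$age),
    cdr_cbf = partial_correlation(used$meta_roi_cbf, used$cdr_sb,
                                  used[, c("age", "education")]),
    cdr_hippo = partial_correlation(used$hippo_norm, used$cdr_sb,
                                    used[, c("age", "education")]),
    stepwise = stepwise_hierarchical(
      used$cdr_sb, used[, c("age", "education")],
      data.frame(cbf = used$meta_roi_cbf, hippo = used$hippo_norm)))
  manifest <- list(
    package = "aslcbf",
    version = as.character(utils::packageVersion("aslcbf")),
    r_version = R.version.string,
    seed = config$seed,
    n_subjects = nrow(cohort),
    n_excluded = sum(!cohort$qc_pass),
    simulate_images = config$simulate_images,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "cleaning_log.txt"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(meta_group_F = stats_res$meta$group_F,
           meta_contrasts = lapply(stats_res$meta$contrasts,
                                   function(ct) ct[c("t", "df", "p",
                                                     "cohens_d")]),
           control_group_F = stats_res$control$group_F,
           cdr_cbf = stats_res$cdr_cbf,
           cdr_hippo = stats_res$cdr_hippo,
           stepwise_entered = stats_res$stepwise$entered),
      file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(cohort = cohort, stats = stats_res,
                 qc_reports = qc_reports, manifest = manifest,
                 log = log_lines))
}

# one subject through the imaging chain
process_one_subject <- function(row, ph, base, config, seed,
                                meta_mask, ctrl_mask, gm_mask) {
  factor_i <- max(row$meta_roi_cbf_true / ph$gm_cbf_true, 0.05)
  cbf_i <- base$cbf_true
  cbf_i[meta_mask] <- cbf_i[meta_mask] * factor_i
  sp <- ph
  sp$seed <- seed
  if (config$n_outlier_volumes > 0) {
    set.seed(seed)
    vols <- sample(2:ph$n_volumes, config$n_outlier_volumes)
    sp$outlier_schedule <- data.frame(volume = vols, type = "noise")
  }
  truth <- ground_truth(cbf_i, base$tissue,
                        outlier_indices = if (is.null(sp$outlier_schedule))
                          integer() else sp$outlier_schedule$volume)
  series <- simulate_subject_series(sp, truth, params = config$quant)
  pp <- preprocess_asl(series, base$tissue, fwhm_mm = config$fwhm_mm,
                       cutoff_hz = config$cutoff_hz,
                       correct_motion = config$correct_motion,
                       protect_alternation = config$protect_alternation)
  dm <- pairwise_subtract(pp$series)
  cbf <- quantify_cbf(dm, m0_volume(series), params = config$quant)
  wb <- apply(matrix(cbf$maps, ncol = dim(cbf$maps)[4])[as.vector(pp$mask), ,
                                                        drop = FALSE],
              2, mean)
  init <- initial_outliers(pp$motion[-1, , drop = FALSE], wb,
                           fd_mm = config$fd_mm, k_sd = config$k_sd_initial)
  cleaned <- adaptive_clean(cbf, gm_mask, cc_floor = config$cc_floor,
                            k_sd = config$k_sd_cc, initial = init)
  final_map <- finalize_cbf(cleaned$cbf)
  qc <- subject_qc(series, final_map, gm_mask, pp$mask,
                   coverage_frac = config$coverage_frac,
                   negativity_frac = config$negativity_frac)
  corrected <- pve_correct(final_map, base$tissue,
                           wm_ratio = config$wm_ratio,
                           gm_floor = config$gm_floor)
  report <- cleaned$report
  report$coverage_ok <- qc$coverage_ok
  report$negativity_ok <- qc$negativity_ok
  reason <- c(if (!qc$coverage_ok) "insufficient brain coverage",
              if (!qc$negativity_ok) "extensive negative GM CBF")
  list(meta_cbf = roi_mean_cbf(corrected, meta_mask, gm_mask),
       control_cbf = roi_mean_cbf(corrected, ctrl_mask, gm_mask),
       qc_pass = qc$coverage_ok && qc$negativity_ok,
       qc_reason = paste(reason, collapse = "; "),
       report = report)
}
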