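# Partial-volume correction, spherical ROI construction, and hippocampal
# volume normalization.

#' Linear partial-volume correction of a GM CBF map
#'
#' For voxels with `P_GM >= gm_floor`, the measured CBF is divided by
#' `P_GM + wm_ratio * P_WM`, treating white matter as perfused at
#' `wm_ratio` (default 0.4) of the gray-matter rate. Voxels below the GM
#' floor are set to 0 and excluded from downstream ROI means via the
#' `"pve_included"` attribute. The correction never changes the sign of
#' CBF, and increases magnitude wherever the denominator is below 1.
#'
#' @param cbf_map 3D CBF map (ml/100 g/min).
#' @param tissue a `tissue_maps` on the same grid.
#' @param wm_ratio assumed WM:GM perfusion ratio (default 0.4).
#' @param gm_floor minimum GM probability for correction (default 0.3).
#' @return corrected 3D array with logical attribute `pve_included`.
#' @export
pve_correct <- function(cbf_map, tissue, wm_ratio = 0.4, gm_floor = 0.3) {
  stopifnot(inherits(tissue, "tissue_maps"),
            identical(dim(cbf_map), dim(tissue$gm)))
  if (wm_ratio < 0) stop("wm_ratio must be non-negative")
  included <- tissue$gm >= gm_floor
  denom <- tissue$gm + wm_ratio * tissue$wm
  out <- array(0, dim = dim(cbf_map))
  out[included] <- cbf_map[included] / denom[included]
  attr(out, "pve_included") <- included
  out
}

#' Define a spherical ROI set
#'
#' @param name label for the ROI set.
#' @param centers numeric matrix (n x 3) of sphere centers in mm (template
#'   space).
#' @param radii sphere radii in mm (recycled to the number of centers).
#' @param role `"meta"` (disease-tracking composite) or `"control"`.
#' @return object of class `roi_spec`.
#' @export
roi_spec <- function(name, centers, radii, role = c("meta", "control")) {
  role <- match.arg(role)
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (nrow(centers) < 1) stop("need at least one sphere")
  radii <- rep_len(as.numeric(radii), nrow(centers))
  if (any(radii <= 0)) stop("sphere radii must be positive")
  structure(list(name = name, centers = centers, radii = radii, role = role),
            class = "roi_spec")
}

#' Rasterize a spherical ROI set into a voxel mask
#'
#' A voxel is included iff its mm center lies within the radius of any
#' sphere (union).
#'
#' @param spec a `roi_spec`.
#' @param dm integer grid dimensions.
#' @param affine 4x4 voxel-to-mm affine.
#' @return logical 3D array.
#' @export
sphere_mask <- function(spec, dm, affine) {
  stopifnot(inherits(spec, "roi_spec"))
  mm <- voxel_centers_mm(dm, affine)
  inside <- rep(FALSE, nrow(mm))
  for (s in seq_len(nrow(spec$centers))) {
    d2 <- (mm[, 1] - spec$centers[s, 1])^2 +
          (mm[, 2] - spec$centers[s, 2])^2 +
          (mm[, 3] - spec$centers[s, 3])^2
    inside <- inside | d2 <= spec$radii[s]^2
  }
  if (!any(inside)) stop("ROI '", spec$name, "' does not intersect the grid")
  array(inside, dim = dm)
}

#' Mean corrected CBF within an ROI
#'
#' Mean over the intersection of the ROI mask, the gray-matter mask, and
#' the voxels retained by [pve_correct()].
#'
#' @param corrected PVE-corrected map (with `pve_included` attribute; a
#'   plain map is treated as fully included).
#' @param roi_mask logical ROI mask.
#' @param gm_mask logical gray-matter mask.
#' @return scalar mean CBF (ml/100 g/min).
#' @export
roi_mean_cbf <- function(corrected, roi_mask, gm_mask) {
  included <- attr(corrected, "pve_included")
  if (is.null(included)) included <- array(TRUE, dim = dim(corrected))
  sel <- roi_mask & gm_mask & included
  if (!any(sel)) stop("ROI/GM intersection is empty after PVE exclusion")
  mean(corrected[sel])
}

#' Normalize hippocampal volume by intracranial volume
#'
#' The average of the left and right hippocampal volumes divided by the
#' intracranial volume (GM + WM + CSF). Dimensionless; scale-invariant.
#'
#' @param left_mm3,right_mm3 hippocampal volumes (mm^3).
#' @param gm_mm3,wm_mm3,csf_mm3 tissue compartment volumes (mm^3).
#' @return scalar normalized hippocampal volume.
#' @export
normalize_hippocampus <- function(left_mm3, right_mm3, gm_mm3, wm_mm3,
                                  csf_mm3) {
  vals <- c(left_mm3, right_mm3, gm_mm3, wm_mm3, csf_mm3)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all volumes must be positive")
  }
  ((left_mm3 + right_mm3) / 2) / (gm_mm3 + wm_mm3 + csf_mm3)
}

#' Write / read spherical ROI configurations as YAML
#'
#' @param specs list of `roi_spec` objects.
#' @param path YAML file path.
#' @return `path` (write) or a list of `roi_spec` (read).
#' @export
write_roi_config <- function(specs, path) {
  if (inherits(specs, "roi_spec")) specs <- list(specs)
  out <- lapply(specs, function(s) {
    list(name = s$name, role = s$role,
         centers = lapply(seq_len(nrow(s$centers)),
                          function(i) as.numeric(s$centers[i, ])),
         radii = as.numeric(s$radii))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_roi_config
#' @export
read_roi_config <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    roi_spec(r$name, do.call(rbind, r$centers), unlist(r$radii), r$role)
  })
}
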