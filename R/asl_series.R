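# Core containers: ASL 4D series, tissue probability maps, and NIfTI I/O.

#' Construct an ASL acquisition series
#'
#' A 4D pulsed-ASL acquisition: the first volume is the equilibrium
#' magnetization (M0) calibration image, followed by strictly alternating
#' label/control volumes.
#'
#' @param data 4D numeric array (x, y, z, volume) in scanner units.
#' @param affine 4x4 voxel-to-mm affine (see [voxel_affine()]).
#' @param volume_labels character vector, one of `"m0"`, `"label"`,
#'   `"control"` per volume. Defaults to M0 followed by label/control pairs.
#' @param tr_ms repetition time in milliseconds.
#' @param first_volume which tag follows M0 when `volume_labels` is built
#'   automatically; the scanner product sequence does not fix this, so it is
#'   configurable. Subtraction is always control minus label.
#' @return object of class `asl_series`.
#' @export
asl_series <- function(data, affine, volume_labels = NULL, tr_ms = 3400,
                       first_volume = c("label", "control")) {
  first_volume <- match.arg(first_volume)
  stopifnot(is.array(data), length(dim(data)) == 4)
  nt <- dim(data)[4]
  if (is.null(volume_labels)) {
    volume_labels <- make_volume_labels(nt, first_volume)
  }
  validate_volume_labels(volume_labels, nt)
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)), tr_ms > 0)
  structure(list(data = data, affine = affine,
                 volume_labels = volume_labels, tr_ms = tr_ms),
            class = "asl_series")
}

#' Default M0 + alternating label/control volume tags
#' @param n_volumes total number of volumes including M0.
#' @param first_volume `"label"` or `"control"`.
#' @return character vector of tags.
#' @export
make_volume_labels <- function(n_volumes, first_volume = c("label", "control")) {
  first_volume <- match.arg(first_volume)
  if (n_volumes < 3 || (n_volumes - 1) %% 2 != 0) {
    stop("n_volumes must be odd (one M0 plus complete label/control pairs)")
  }
  other <- if (first_volume == "label") "control" else "label"
  c("m0", rep(c(first_volume, other), (n_volumes - 1) / 2))
}

validate_volume_labels <- function(labels, nt) {
  if (length(labels) != nt) stop("volume_labels length must equal n volumes")
  if (labels[1] != "m0") stop("first volume must be tagged 'm0'")
  rest <- labels[-1]
  if (!all(rest %in% c("label", "control"))) {
    stop("non-M0 volumes must be tagged 'label' or 'control'")
  }
  if (length(rest) %% 2 != 0) stop("label/control volumes must come in pairs")
  if (any(rest[-1] == rest[-length(rest)])) {
    stop("label/control tags must strictly alternate")
  }
  invisible(TRUE)
}

#' @export
print.asl_series <- function(x, ...) {
  d <- dim(x$data)
  vx <- diag(x$affine)[1:3]
  cat(sprintf("<asl_series> %dx%dx%d grid, %d volumes (1 M0 + %d pairs)\n",
              d[1], d[2], d[3], d[4], (d[4] - 1) / 2))
  cat(sprintf("  voxels %.2f x %.2f x %.2f mm, TR %g ms, first tag '%s'\n",
              vx[1], vx[2], vx[3], x$tr_ms, x$volume_labels[2]))
  invisible(x)
}

#' Extract the M0 calibration volume
#' @param series an `asl_series`.
#' @return 3D array.
#' @export
m0_volume <- function(series) {
  stopifnot(inherits(series, "asl_series"))
  series$data[, , , which(series$volume_labels == "m0")[1]]
}

#' Construct co-registered tissue probability maps
#'
#' @param gm,wm,csf 3D probability arrays on a shared grid; the per-voxel sum
#'   may be below 1 (background).
#' @param affine 4x4 voxel-to-mm affine.
#' @return object of class `tissue_maps`.
#' @export
tissue_maps <- function(gm, wm, csf, affine) {
  stopifnot(identical(dim(gm), dim(wm)), identical(dim(gm), dim(csf)))
  rng <- range(gm, wm, csf)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8) {
    stop("tissue probabilities must lie in [0, 1]")
  }
  tot <- gm + wm + csf
  if (max(tot) > 1 + 1e-6) stop("tissue probabilities must sum to <= 1 per voxel")
  structure(list(gm = gm, wm = wm, csf = csf, affine = affine),
            class = "tissue_maps")
}

#' Threshold one tissue class into a binary mask
#' @param tissue a `tissue_maps` object.
#' @param class `"gm"`, `"wm"` or `"csf"`.
#' @param threshold probability threshold (exclusive).
#' @return logical 3D array.
#' @export
tissue_mask <- function(tissue, class = c("gm", "wm", "csf"), threshold = 0.3) {
  class <- match.arg(class)
  tissue[[class]] > threshold
}

#' @export
print.tissue_maps <- function(x, ...) {
  d <- dim(x$gm)
  cat(sprintf("<tissue_maps> %dx%dx%d; GM/WM/CSF voxels (p>0.5): %d/%d/%d\n",
              d[1], d[2], d[3], sum(x$gm > 0.5), sum(x$wm > 0.5),
              sum(x$csf > 0.5)))
  invisible(x)
}

#' Write an ASL series (or a 3D map) as NIfTI-1
#'
#' @param x an `asl_series` or a 3D/4D array.
#' @param path output `.nii` / `.nii.gz` path. For an `asl_series` a JSON
#'   sidecar with the volume tags and TR is written next to it.
#' @param affine affine for plain arrays (ignored for `asl_series`).
#' @return `path`, invisibly.
#' @export
write_asl_nifti <- function(x, path, affine = NULL) {
  if (inherits(x, "asl_series")) {
    img <- RNifti::asNifti(x$data)
    RNifti::sform(img) <- structure(x$affine, code = 2L)
    RNifti::writeNifti(img, path)
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(list(volume_labels = x$volume_labels,
                              tr_ms = x$tr_ms),
                         sidecar, auto_unbox = TRUE, digits = NA)
  } else {
    img <- RNifti::asNifti(x)
    if (!is.null(affine)) RNifti::sform(img) <- structure(affine, code = 2L)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read an ASL series written by [write_asl_nifti()]
#' @param path NIfTI path; the JSON sidecar must be present.
#' @return an `asl_series`.
#' @export
read_asl_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  aff <- unclass(RNifti::xform(img))
  asl_series(array(as.numeric(img), dim = dim(img)), affine = aff,
             volume_labels = meta$volume_labels, tr_ms = meta$tr_ms)
}
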