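#' Volume and mask containers
#'
#' A `volume_grid` is a 3D numeric array of intensities (HU or arbitrary
#' units) together with its physical voxel spacing in millimetres. A
#' `roi_mask` is a congruent 3D logical array marking the region of
#' interest. A `labeled_volume` bundles a volume, its nodule mask, a
#' benign/malignant label and an identifier, and is the unit that flows
#' through setting simulation and feature extraction.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric length-3 vector of voxel spacing (mm), all > 0.
#' @param origin numeric length-3 physical origin (mm).
#' @return `volume_grid()` returns an object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  if (!all(is.finite(data))) stop("volume intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three strictly positive values")
  }
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @param voxels 3D array coercible to logical.
#' @rdname volume_grid
#' @return `roi_mask()` returns an object of class `roi_mask`.
#' @export
roi_mask <- function(voxels) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("mask must be a 3D array")
  structure(list(voxels = array(as.logical(voxels), dim(voxels))),
            class = "roi_mask")
}

#' @param volume a `volume_grid`.
#' @param mask a `roi_mask` congruent with `volume`.
#' @param label `"benign"` or `"malignant"`.
#' @param nodule_id identifier string.
#' @param diameter_mm equivalent-sphere diameter used to generate the nodule
#'   (recorded for the cohort manifest; `NA` for real data).
#' @rdname volume_grid
#' @return `labeled_volume()` returns an object of class `labeled_volume`.
#' @export
labeled_volume <- function(volume, mask, label, nodule_id,
                           diameter_mm = NA_real_) {
  stopifnot(inherits(volume, "volume_grid"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$data), dim(mask$voxels))) {
    stop("mask lattice must be congruent with the volume lattice")
  }
  if (!any(mask$voxels)) stop("mask must be nonempty")
  label <- match.arg(label, c("benign", "malignant"))
  structure(list(volume = volume, mask = mask, label = label,
                 nodule_id = as.character(nodule_id),
                 diameter_mm = diameter_mm),
            class = "labeled_volume")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s (%s), %d ROI voxels, grid %s\n",
              x$nodule_id, x$label, sum(x$mask$voxels),
              paste(dim(x$volume$data), collapse = "x")))
  invisible(x)
}
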