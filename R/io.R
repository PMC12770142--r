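#' Write and read cohort volumes as NIfTI
#'
#' Writes each nodule's volume and mask as compressed NIfTI files
#' (`<id>_image.nii.gz`, `<id>_mask.nii.gz`) with the voxel spacing in the
#' header, plus a `manifest.csv` (nodule_id, label, diameter_mm, file
#' names). Requires the suggested `RNifti` package.
#'
#' @param cohort list of [labeled_volume()]s.
#' @param dir output directory (created if needed).
#' @return `write_cohort_nifti()` returns the manifest data.frame
#'   (invisibly); `read_labeled_volume()` returns a [labeled_volume()].
#' @export
write_cohort_nifti <- function(cohort, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_cohort_nifti() requires the 'RNifti' package")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort_manifest(cohort)
  manifest$image <- paste0(manifest$nodule_id, "_image.nii.gz")
  manifest$mask <- paste0(manifest$nodule_id, "_mask.nii.gz")
  for (i in seq_along(cohort)) {
    lv <- cohort[[i]]
    img <- RNifti::asNifti(lv$volume$data)
    RNifti::pixdim(img) <- lv$volume$spacing
    RNifti::writeNifti(img, file.path(dir, manifest$image[i]))
    msk <- RNifti::asNifti(lv$mask$voxels * 1L)
    RNifti::pixdim(msk) <- lv$volume$spacing
    RNifti::writeNifti(msk, file.path(dir, manifest$mask[i]))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @param image_path,mask_path NIfTI file paths.
#' @param label,nodule_id metadata attached to the loaded pair.
#' @rdname write_cohort_nifti
#' @export
read_labeled_volume <- function(image_path, mask_path, label = "benign",
                                nodule_id = "N0001") {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_labeled_volume() requires the 'RNifti' package")
  }
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  labeled_volume(volume_grid(array(as.numeric(img), dim(img)), spacing),
                 roi_mask(array(msk > 0.5, dim(msk))),
                 label = label, nodule_id = nodule_id)
}
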