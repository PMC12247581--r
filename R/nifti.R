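#' Write a volume (or phantom cohort) to NIfTI
#'
#' Volumes are written as `.nii.gz` with the voxel spacing in the header
#' (phantoms default to 1 mm isotropic).
#'
#' @param x a `volume_image`, bare 3D array, or `phantom_cohort`.
#' @param path output file (volume) or directory (cohort).
#' @return For a cohort: invisibly, the metadata tibble (subject_id, age,
#'   sex, path) that was also written as `cohort.csv`. Otherwise the path.
#' @export
write_volume_nifti <- function(x, path) {
  if (inherits(x, "phantom_cohort")) {
    dir.create(path, recursive = TRUE, showWarnings = FALSE)
    meta <- x$subjects
    meta$path <- file.path(path, paste0(meta$subject_id, ".nii.gz"))
    for (i in seq_len(nrow(meta))) {
      write_volume_nifti(volume_image(x$volumes[[i]]), meta$path[i])
    }
    write.csv(meta, file.path(path, "cohort.csv"), row.names = FALSE)
    return(invisible(meta))
  }
  v <- as_volume_image(x)
  img <- RNifti::asNifti(v$data, pixdim = v$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @return a `volume_image` with spacing taken from the header.
#' @export
read_volume_nifti <- function(path) {
  if (!file.exists(path)) abort(sprintf("NIfTI file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf(
                    "failed to read NIfTI `%s`: %s", path, conditionMessage(e))))
  volume_image(array(as.numeric(img), dim = dim(img)),
               RNifti::pixdim(img)[seq_len(3)])
}
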