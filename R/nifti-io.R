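# NIfTI-1 reading/writing via RNifti. The affine is stored in both qform and
# sform (code 2, "aligned"); on read the sform is taken verbatim.

nifti_from_volume <- function(data, affine) {
  img <- RNifti::asNifti(data)
  img$pixdim <- c(1, sqrt(colSums(affine[1:3, 1:3]^2)), 1, 0, 0, 0)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img
}

# RNifti expects 0-based voxel indices in its xforms; our containers use
# 1-based indices, so shift the translation column on the way in and out.
affine_1based_to_nifti <- function(affine) {
  affine[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% c(1, 1, 1)
  affine
}

affine_nifti_to_1based <- function(affine) {
  affine[1:3, 4] <- affine[1:3, 4] - affine[1:3, 1:3] %*% c(1, 1, 1)
  affine
}

#' Write an SUV or label volume to NIfTI-1
#'
#' @param volume An `suv_volume` or `label_volume`.
#' @param path Output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, c("suv_volume", "label_volume")))
  data <- volume$data
  if (inherits(volume, "label_volume")) storage.mode(data) <- "integer"
  img <- nifti_from_volume(data, affine_1based_to_nifti(volume$affine))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an SUV volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param t_min Acquisition time post-injection (min) to attach.
#' @param dose_MBq,weight_kg,patient_id Optional scan metadata to attach.
#' @return An `suv_volume`.
#' @export
read_suv_volume <- function(path, t_min = NA_real_, dose_MBq = NA_real_,
                            weight_kg = NA_real_, patient_id = NA_character_) {
  img <- RNifti::readNifti(path)
  aff <- affine_nifti_to_1based(unclass_affine(RNifti::xform(img, useQuaternionFirst = FALSE)))
  new_suv_volume(plain_array(img), aff, t_min = t_min, dose_MBq = dose_MBq,
                 weight_kg = weight_kg, patient_id = patient_id)
}

#' Read a label volume from NIfTI-1
#'
#' @param path NIfTI file path containing integer labels.
#' @param pairs Left/right pairing table (tibble with columns `region`,
#'   `lh_label`, `rh_label`, `lh_name`, `rh_name`), e.g. from a phantom's
#'   `$pairs`, or `NULL` if pairing is supplied later.
#' @return A `label_volume`.
#' @export
read_label_volume <- function(path, pairs = NULL) {
  img <- RNifti::readNifti(path)
  aff <- affine_nifti_to_1based(unclass_affine(RNifti::xform(img, useQuaternionFirst = FALSE)))
  arr <- plain_array(img)
  storage.mode(arr) <- "integer"
  new_label_volume(arr, aff, pairs, voxel_mm = sqrt(sum(aff[1:3, 1]^2)))
}

unclass_affine <- function(x) {
  matrix(as.numeric(x), 4, 4)
}

# strip RNifti pointers/attributes down to a bare array
plain_array <- function(img) {
  arr <- as.array(img)
  array(as.vector(arr), dim = dim(arr))
}
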