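check_same_grid <- function(image, labels) {
  if (!identical(dim(image$data), dim(labels$data)) ||
      !affines_match(image$affine, labels$affine)) {
    stop_dtpet(paste0(
      "Image and label grids differ; resample the labels onto the PET grid ",
      "first with resample_labels(labels, image$affine, dim(image$data))."
    ), "dtpet_geometry_error")
  }
}

resolve_labels <- function(labels, label) {
  if (is.character(label)) {
    p <- labels$pairs
    lut <- stats::setNames(c(p$lh_label, p$rh_label), c(p$lh_name, p$rh_name))
    unknown <- setdiff(label, names(lut))
    if (length(unknown)) {
      stop_dtpet(paste0("Unknown region name(s): ",
                        paste(unknown, collapse = ", "), ". Available: ",
                        paste(names(lut), collapse = ", ")),
                 "dtpet_lookup_error")
    }
    unname(lut[label])
  } else {
    as.integer(label)
  }
}

#' Regional SUVmean for one region (or a union of regions)
#'
#' Arithmetic mean of image voxels whose label matches; for a union of labels
#' the mean is voxel-weighted (one pooled mean over all member voxels, not a
#' mean of per-region means). Background (label 0) is never included.
#'
#' @param image An `suv_volume` on the same grid as `labels`.
#' @param labels A `label_volume` (resample first if grids differ).
#' @param label Integer label id(s) or region name(s); several ids form a
#'   union region.
#' @return A one-row tibble: `label`, `region`, `n_voxels`, `suvmean`, `t_min`.
#' @examples
#' lab <- build_labels(phantom_spec(shape = c(24, 24, 20), n_regions = 2))
#' kin <- stats::setNames(rep(list(kinetic_params()), 4), c(1, 2, 101, 102))
#' img <- synthesize_suv_volume(lab, kin, feng_input(), dose_MBq = 240,
#'                              weight_kg = 65, t = 45)
#' extract_suvmean(img, lab, "lh_roi_1")
#' @export
extract_suvmean <- function(image, labels, label) {
  stopifnot(inherits(image, "suv_volume"), inherits(labels, "label_volume"))
  check_same_grid(image, labels)
  ids <- resolve_labels(labels, label)
  present <- sort(unique(as.integer(labels$data[labels$data > 0])))
  absent <- setdiff(ids, present)
  if (length(absent)) {
    stop_dtpet(paste0("Label(s) ", paste(absent, collapse = ", "),
                      " not present. Available labels: ",
                      paste(present, collapse = ", ")),
               "dtpet_lookup_error")
  }
  mask <- labels$data %in% ids
  tibble(
    label = paste(ids, collapse = "+"),
    region = paste(label_name(labels, ids), collapse = "+"),
    n_voxels = sum(mask),
    suvmean = mean(image$data[mask]),
    t_min = image$t_min
  )
}

#' Regional SUVmean table for every region
#'
#' @inheritParams extract_suvmean
#' @return A tibble with one row per non-background label: `label`, `region`,
#'   `n_voxels`, `suvmean`, `t_min`.
#' @export
suvmean_table <- function(image, labels) {
  stopifnot(inherits(image, "suv_volume"), inherits(labels, "label_volume"))
  check_same_grid(image, labels)
  lv <- as.integer(labels$data)
  keep <- lv > 0
  sums <- tapply(image$data[keep], lv[keep], sum)
  ns <- tapply(rep(1L, sum(keep)), lv[keep], sum)
  ids <- as.integer(names(sums))
  tibble(
    label = ids,
    region = label_name(labels, ids),
    n_voxels = as.integer(ns),
    suvmean = as.numeric(sums / ns),
    t_min = image$t_min
  )
}

#' SUVmean pair for the EZ region and its contralateral mirror
#'
#' Looks up the mirror partner(s) of the epileptogenic-zone label(s) in the
#' pairing table and returns both pooled SUVmeans at the image's acquisition
#' time — the inputs of the asymmetry index.
#'
#' @inheritParams extract_suvmean
#' @param ez EZ label id(s) or region name(s); a vector denotes a union.
#' @return A one-row tibble: `ez_label`, `contra_label`, `suv_ez`,
#'   `suv_contra`, `n_voxels_ez`, `n_voxels_contra`, `t_min`.
#' @export
paired_suvmeans <- function(image, labels, ez) {
  ez_ids <- resolve_labels(labels, ez)
  contra_ids <- mirror_label(labels, ez_ids)
  ez_row <- extract_suvmean(image, labels, ez_ids)
  co_row <- extract_suvmean(image, labels, contra_ids)
  tibble(
    ez_label = ez_row$label, contra_label = co_row$label,
    suv_ez = ez_row$suvmean, suv_contra = co_row$suvmean,
    n_voxels_ez = ez_row$n_voxels, n_voxels_contra = co_row$n_voxels,
    t_min = image$t_min
  )
}

#' Long table of per-patient regional SUVmeans for a cohort
#'
#' For voxel-mode cohorts the table is extracted from the synthesized volumes;
#' regional-mode cohorts carry it directly.
#'
#' @param cohort A `pet_cohort` from [simulate_cohort()].
#' @return A tibble: `patient_id`, `timepoint`, `label`, `region`,
#'   `n_voxels`, `suvmean`, `t_min`.
#' @export
quantify_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "pet_cohort"))
  cohort$regional
}
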