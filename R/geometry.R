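# Volume containers and resampling.
#
# A volume is a light list: `data` (3-D array), `affine` (4x4 voxel->world,
# RAS mm, 1-based voxel indices), plus type-specific fields. Interpolation is
# implemented here because no installed package offers 3-D rigid resampling;
# conventions: trilinear for intensities, nearest-neighbour for labels with
# half-voxel ties resolved toward the lower index.

#' Construct an SUV volume
#'
#' @param data 3-D numeric array of SUV values.
#' @param affine 4x4 voxel-to-world affine (RAS mm, 1-based voxel indices).
#' @param t_min Acquisition time post-injection (min).
#' @param dose_MBq,weight_kg,patient_id Optional scan metadata.
#' @return An object of class `"suv_volume"`.
#' @export
new_suv_volume <- function(data, affine, t_min, dose_MBq = NA_real_,
                           weight_kg = NA_real_, patient_id = NA_character_) {
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  structure(list(data = data, affine = affine, t_min = t_min,
                 dose_MBq = dose_MBq, weight_kg = weight_kg,
                 patient_id = patient_id),
            class = "suv_volume")
}

#' Construct a label volume
#'
#' @param data 3-D integer array of region labels (0 = background).
#' @param affine 4x4 voxel-to-world affine (RAS mm, 1-based voxel indices).
#' @param pairs Left/right pairing tibble (`region`, `lh_label`, `rh_label`,
#'   `lh_name`, `rh_name`).
#' @param voxel_mm Isotropic voxel size (mm).
#' @return An object of class `"label_volume"`.
#' @export
new_label_volume <- function(data, affine, pairs, voxel_mm) {
  stopifnot(length(dim(data)) == 3, all(dim(affine) == c(4, 4)))
  structure(list(data = data, affine = affine, pairs = pairs,
                 voxel_mm = voxel_mm),
            class = "label_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("SUV volume %dx%dx%d, t = %.4g min post-injection\n",
              d[1], d[2], d[3], x$t_min))
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Label volume %dx%dx%d, %d paired regions/hemisphere\n",
              d[1], d[2], d[3], nrow(x$pairs)))
  invisible(x)
}

# voxel (1-based, n x 3) -> world (n x 3)
voxel_to_world <- function(affine, ijk) {
  xyz1 <- cbind(ijk, 1) %*% t(affine)
  xyz1[, 1:3, drop = FALSE]
}

world_to_voxel <- function(affine, xyz) {
  inv <- solve(affine)
  ijk1 <- cbind(xyz, 1) %*% t(inv)
  ijk1[, 1:3, drop = FALSE]
}

# All voxel centers of a grid as an n x 3 matrix of 1-based indices.
grid_indices <- function(shape) {
  as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                        k = seq_len(shape[3]), KEEP.OUT.ATTRS = FALSE))
}

affines_match <- function(a, b, tol = 1e-6) {
  max(abs(a - b)) <= tol
}

# Trilinear sampling of `arr` at continuous 1-based indices (n x 3).
# Out-of-field corners contribute 0 (zero fill).
sample_trilinear <- function(arr, ijk) {
  d <- dim(arr)
  i0 <- floor(ijk)
  fr <- ijk - i0
  out <- numeric(nrow(ijk))
  for (corner in 0:7) {
    off <- c(corner %% 2, (corner %/% 2) %% 2, corner %/% 4)
    ci <- i0[, 1] + off[1]; cj <- i0[, 2] + off[2]; ck <- i0[, 3] + off[3]
    w <- (if (off[1]) fr[, 1] else 1 - fr[, 1]) *
         (if (off[2]) fr[, 2] else 1 - fr[, 2]) *
         (if (off[3]) fr[, 3] else 1 - fr[, 3])
    ok <- ci >= 1 & ci <= d[1] & cj >= 1 & cj <= d[2] & ck >= 1 & ck <= d[3] & w > 0
    if (any(ok)) {
      lin <- ci[ok] + (cj[ok] - 1) * d[1] + (ck[ok] - 1) * d[1] * d[2]
      out[ok] <- out[ok] + w[ok] * arr[lin]
    }
  }
  out
}

# Nearest-neighbour sampling; half-voxel ties go to the lower index.
sample_nearest <- function(arr, ijk) {
  d <- dim(arr)
  idx <- ceiling(ijk - 0.5)
  out <- numeric(nrow(ijk))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (any(ok)) {
    lin <- idx[ok, 1] + (idx[ok, 2] - 1) * d[1] + (idx[ok, 3] - 1) * d[1] * d[2]
    out[ok] <- arr[lin]
  }
  out
}

rotation_matrix <- function(rotation_deg) {
  th <- rotation_deg * pi / 180
  cx <- cos(th[1]); sx <- sin(th[1])
  cy <- cos(th[2]); sy <- sin(th[2])
  cz <- cos(th[3]); sz <- sin(th[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a known rigid transform to an SUV volume
#'
#' Resamples the volume under a rigid-body motion (rotation about the volume's
#' world center followed by translation) with trilinear interpolation, onto
#' the same voxel grid. Voxels mapped from outside the original field of view
#' are filled with 0. Only *application* of a known transform is provided;
#' transform estimation (registration) is out of scope.
#'
#' @param volume An `suv_volume`.
#' @param translation Translation (mm), length-3 (x, y, z in world axes).
#' @param rotation Rotation (degrees), length-3, applied as Rz Ry Rx about the
#'   volume's world center.
#' @return A resampled `suv_volume` on the same grid.
#' @export
apply_rigid <- function(volume, translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  stopifnot(inherits(volume, "suv_volume"))
  if (!all(is.finite(c(translation, rotation))) ||
      length(translation) != 3 || length(rotation) != 3) {
    stop_dtpet("translation and rotation must be finite length-3 vectors.",
               "dtpet_geometry_error")
  }
  if (all(translation == 0) && all(rotation == 0)) return(volume)
  d <- dim(volume$data)
  center <- colMeans(voxel_to_world(
    volume$affine, rbind(c(1, 1, 1), d)))
  R <- rotation_matrix(rotation)
  ijk <- grid_indices(d)
  w <- voxel_to_world(volume$affine, ijk)
  # output(v) = input(T^{-1} v): invert the forward motion
  src <- sweep(w, 2, center + translation) %*% R  # == t(R^-1 %*% t(...)) for rigid R
  src <- sweep(src, 2, center, FUN = "+")
  sijk <- world_to_voxel(volume$affine, src)
  vals <- sample_trilinear(volume$data, sijk)
  out <- volume
  out$data <- array(vals, dim = d)
  out
}

#' Resample a label volume onto a target grid
#'
#' Maps integer labels onto a new grid through world coordinates with
#' nearest-neighbour interpolation (the standard choice for categorical
#' images); ties at exact half-voxel boundaries resolve toward the lower
#' index. The left/right pairing table is carried over unchanged. Labels are
#' always resampled to the PET grid, never PET intensities to the label grid,
#' so intensities are never interpolated before averaging.
#'
#' @param labels A `label_volume`.
#' @param target_affine 4x4 voxel-to-world affine of the target grid.
#' @param target_shape Integer length-3 target grid dimensions.
#' @return A `label_volume` on the target grid.
#' @export
resample_labels <- function(labels, target_affine, target_shape) {
  stopifnot(inherits(labels, "label_volume"))
  if (abs(det(target_affine[1:3, 1:3])) < .Machine$double.eps * 100 ||
      abs(det(labels$affine[1:3, 1:3])) < .Machine$double.eps * 100) {
    stop_dtpet("Affine is not invertible.", "dtpet_geometry_error")
  }
  ijk <- grid_indices(target_shape)
  w <- voxel_to_world(target_affine, ijk)
  sijk <- world_to_voxel(labels$affine, w)
  vals <- sample_nearest(labels$data, sijk)
  new_label_volume(array(as.integer(vals), dim = target_shape),
                   target_affine, labels$pairs,
                   voxel_mm = sqrt(sum(target_affine[1:3, 1]^2)))
}
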