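make_const_image <- function(labels, values) {
  # piecewise-constant image: values named by label
  arr <- array(0, dim = dim(labels$data))
  for (l in names(values)) arr[labels$data == as.integer(l)] <- values[[l]]
  new_suv_volume(arr, labels$affine, t_min = 45)
}

test_that("regional SUVmean is the arithmetic mean over the labelled voxels", {
  lab <- small_labels()
  img <- make_const_image(lab, list(`1` = 4, `2` = 2, `101` = 6, `102` = 1))
  expect_equal(extract_suvmean(img, lab, 1)$suvmean, 4)
  expect_equal(extract_suvmean(img, lab, "rh_roi_1")$suvmean, 6)

  # two-voxel region valued 4 and 6 -> 5
  arr <- array(0L, dim = c(16, 16, 16))
  arr[8, 8, 8] <- 1L; arr[9, 8, 8] <- 1L; arr[4, 8, 8] <- 2L
  tiny <- new_label_volume(arr, diag(4), tibble::tibble(
    region = 1:2, lh_label = 1:2, rh_label = c(101L, 102L),
    lh_name = c("lh_a", "lh_b"), rh_name = c("rh_a", "rh_b")), 1)
  vals <- array(0, dim = c(16, 16, 16)); vals[8, 8, 8] <- 4; vals[9, 8, 8] <- 6
  vimg <- new_suv_volume(vals, diag(4), t_min = 45)
  got <- extract_suvmean(vimg, tiny, 1)
  expect_equal(got$suvmean, 5)
  expect_equal(got$n_voxels, 2L)

  # absent label -> lookup error listing what exists
  expect_error(extract_suvmean(img, lab, 55), "Available labels",
               class = "dtpet_lookup_error")
  # grid mismatch -> geometry error telling the caller to resample
  off <- img; off$affine[1, 4] <- off$affine[1, 4] + 1
  expect_error(extract_suvmean(off, lab, 1), "resample_labels",
               class = "dtpet_geometry_error")
})

test_that("SUVmean is invariant to voxel storage order and conserves totals", {
  lab <- small_labels()
  img <- synthesize_suv_volume(lab, uniform_kinetics(lab, kinetic_params()),
                               feng_input(), 240, 65, t = 45, sigma = 0.05,
                               seed = 21)
  base <- suvmean_table(img, lab)
  # permute all voxels consistently (array relayout through aperm)
  perm_img <- img; perm_lab <- lab
  perm_img$data <- aperm(img$data, c(2, 1, 3))
  perm_lab$data <- aperm(lab$data, c(2, 1, 3))
  # world geometry changed identically for both, so means are untouched
  perm_img$affine <- perm_lab$affine <- diag(4)
  perm <- suvmean_table(perm_img, perm_lab)
  expect_equal(perm$suvmean, base$suvmean)
  expect_equal(perm$n_voxels, base$n_voxels)

  # conservation: sum over regions of n * mean == image total over the mask
  expect_equal(sum(base$n_voxels * base$suvmean),
               sum(img$data[lab$data > 0]))
})

test_that("label resampling preserves identity, aligned downsampling and centroids", {
  lab <- small_labels()
  # identical grids -> identical labels
  same <- resample_labels(lab, lab$affine, dim(lab$data))
  expect_identical(same$data, lab$data)

  # grid-aligned half-space field survives 2x downsampling exactly
  d <- c(16, 16, 16)
  arr <- array(0L, dim = d)
  arr[1:8, , ] <- 1L; arr[9:16, , ] <- 101L
  aff <- diag(4); aff[1:3, 4] <- -1  # world = idx - 1 - ... keep simple: world=idx-1
  half <- new_label_volume(arr, aff, tibble::tibble(
    region = 1L, lh_label = 1L, rh_label = 101L,
    lh_name = "lh_a", rh_name = "rh_a"), 1)
  target_aff <- aff %*% diag(c(2, 2, 2, 1))
  target_aff[1:3, 4] <- aff[1:3, 4] - 0.5  # voxel centers at pairwise midpoints
  down <- resample_labels(half, target_aff, c(8, 8, 8))
  expect_true(all(down$data[1:4, , ] == 1L))
  expect_true(all(down$data[5:8, , ] == 101L))

  # SUVmean of a piecewise-constant image is invariant under nested-grid
  # downsampling of the labels when the image is averaged on the source grid
  img <- make_const_image(lab, list(`1` = 4, `2` = 2, `101` = 6, `102` = 1))
  up <- resample_labels(resample_labels(lab, lab$affine, dim(lab$data)),
                        lab$affine, dim(lab$data))
  expect_equal(extract_suvmean(img, up, 1)$suvmean, 4)

  # centroids move by less than one target voxel under 2x downsampling
  src_aff <- lab$affine
  tgt_aff <- src_aff %*% diag(c(2, 2, 2, 1))
  tgt_aff[1:3, 4] <- src_aff[1:3, 4] - src_aff[1, 1] / 2
  tgt_shape <- dim(lab$data) %/% 2
  down2 <- resample_labels(lab, tgt_aff, tgt_shape)
  centroid <- function(vol, l) {
    idx <- which(vol$data == l, arr.ind = TRUE)
    colMeans(dtpet:::voxel_to_world(vol$affine, idx))
  }
  for (l in c(1, 2, 101, 102)) {
    shift <- sqrt(sum((centroid(lab, l) - centroid(down2, l))^2))
    expect_lt(shift, 2 * src_aff[1, 1])  # one target voxel = 2 source voxels
  }

  expect_error(resample_labels(half, matrix(0, 4, 4), c(8, 8, 8)),
               class = "dtpet_geometry_error")
})

test_that("paired extraction mirrors the EZ and swaps with hemisphere", {
  lab <- small_labels()
  kp <- kinetic_params()
  ez_kp <- kinetic_params(kp$K1 * 0.92, kp$k2, kp$k3 * 0.75)

  # symmetric phantom -> equal pair
  sym <- synthesize_suv_volume(lab, uniform_kinetics(lab, kp), feng_input(),
                               240, 65, t = 45)
  p <- paired_suvmeans(sym, lab, 1)
  expect_equal(p$suv_ez, p$suv_contra)

  # hypometabolic left EZ -> lower than contralateral; swapping hemisphere swaps
  left <- synthesize_suv_volume(lab, uniform_kinetics(lab, kp, 1, ez_kp),
                                feng_input(), 240, 65, t = 45)
  right <- synthesize_suv_volume(lab, uniform_kinetics(lab, kp, 101, ez_kp),
                                 feng_input(), 240, 65, t = 45)
  pl <- paired_suvmeans(left, lab, 1)
  pr <- paired_suvmeans(right, lab, 101)
  expect_lt(pl$suv_ez, pl$suv_contra)
  expect_equal(pl$suv_ez, pr$suv_ez)
  expect_equal(pl$suv_contra, pr$suv_contra)

  # union EZ is voxel-weighted, not a mean of means
  u <- extract_suvmean(left, lab, c(1, 2))
  s1 <- extract_suvmean(left, lab, 1); s2 <- extract_suvmean(left, lab, 2)
  expect_equal(u$suvmean,
               (s1$suvmean * s1$n_voxels + s2$suvmean * s2$n_voxels) /
                 (s1$n_voxels + s2$n_voxels))

  expect_error(paired_suvmeans(left, lab, 999), class = "dtpet_pairing_error")
})

test_that("NIfTI round trip preserves data and world geometry", {
  lab <- small_labels()
  img <- synthesize_suv_volume(lab, uniform_kinetics(lab, kinetic_params()),
                               feng_input(), 240, 65, t = 45, sigma = 0.02,
                               seed = 8)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(img, f)
  back <- read_suv_volume(f, t_min = 45)
  expect_equal(back$data, unclass(img$data), tolerance = 1e-6)
  expect_equal(back$affine, img$affine, tolerance = 1e-5)

  fl <- tempfile(fileext = ".nii.gz")
  write_volume(lab, fl)
  lab_back <- read_label_volume(fl, pairs = lab$pairs)
  expect_identical(lab_back$data, lab$data)
})
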