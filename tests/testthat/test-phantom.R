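test_that("label phantom is mirror symmetric with paired regions", {
  lab <- small_labels()
  counts <- table(lab$data[lab$data > 0])
  # every lh region's voxel count equals its rh mirror's
  for (r in seq_len(nrow(lab$pairs))) {
    expect_equal(unname(counts[as.character(lab$pairs$lh_label[r])]),
                 unname(counts[as.character(lab$pairs$rh_label[r])]))
  }
  # mirror-flip about the midline equals the lh/rh label swap
  flipped <- lab$data[dim(lab$data)[1]:1, , ]
  swapped <- lab$data
  for (r in seq_len(nrow(lab$pairs))) {
    swapped[lab$data == lab$pairs$lh_label[r]] <- lab$pairs$rh_label[r]
    swapped[lab$data == lab$pairs$rh_label[r]] <- lab$pairs$lh_label[r]
  }
  expect_identical(flipped, swapped)

  one <- build_labels(phantom_spec(shape = c(24, 24, 20), n_regions = 1))
  expect_setequal(unique(as.integer(one$data)), c(0L, 1L, 101L))

  # too many regions for the grid -> tiny regions rejected
  expect_error(build_labels(phantom_spec(shape = c(16, 16, 16), n_regions = 60)),
               class = "dtpet_spec_error")
  expect_error(phantom_spec(shape = c(8, 8, 8)), class = "dtpet_spec_error")
})

test_that("synthesized volumes realize the scalar kinetic prediction", {
  lab <- small_labels()
  inp <- feng_input()
  kp <- kinetic_params()
  ez_kp <- kinetic_params(K1 = kp$K1 * 0.92, k2 = kp$k2, k3 = kp$k3 * 0.75)
  dose <- 240; wt <- 65

  # K1 = 0 everywhere -> all-zero image
  zero <- synthesize_suv_volume(lab, uniform_kinetics(lab, kinetic_params(0, 0.1, 0.05)),
                                inp, dose, wt, t = 45)
  expect_identical(unique(as.numeric(zero$data)), 0)

  # noise-free regional mean equals the scalar prediction
  img <- synthesize_suv_volume(lab, uniform_kinetics(lab, kp), inp, dose, wt, t = 45)
  pred <- suv_from_activity(tissue_activity(kp, inp, 45), dose, wt)
  for (l in c(1, 102)) {
    expect_equal(extract_suvmean(img, lab, l)$suvmean, pred, tolerance = 1e-12)
  }

  # hypometabolic EZ: lower than contralateral at both times, wider gap late
  kin <- uniform_kinetics(lab, kp, override_label = 1, override_kp = ez_kp)
  early <- synthesize_suv_volume(lab, kin, inp, dose, wt, t = 43)
  late <- synthesize_suv_volume(lab, kin, inp, dose, wt, t = 160)
  gap <- function(img) {
    p <- paired_suvmeans(img, lab, 1)
    c(ez = p$suv_ez, contra = p$suv_contra,
      rel = (p$suv_contra - p$suv_ez) / p$suv_contra)
  }
  g43 <- gap(early); g160 <- gap(late)
  expect_lt(g43[["ez"]], g43[["contra"]])
  expect_lt(g160[["ez"]], g160[["contra"]])
  expect_gt(g160[["rel"]], g43[["rel"]])

  # missing kinetics is a configuration error
  expect_error(synthesize_suv_volume(lab, uniform_kinetics(lab, kp)[-1], inp,
                                     dose, wt, t = 45),
               class = "dtpet_config_error")
})

test_that("noise is reproducible from the seed and scales with the mean", {
  lab <- small_labels()
  kin <- uniform_kinetics(lab, kinetic_params())
  a <- synthesize_suv_volume(lab, kin, feng_input(), 240, 65, t = 45,
                             sigma = 0.05, seed = 11)
  b <- synthesize_suv_volume(lab, kin, feng_input(), 240, 65, t = 45,
                             sigma = 0.05, seed = 11)
  expect_identical(a$data, b$data)
  mu <- suv_from_activity(tissue_activity(kinetic_params(), feng_input(), 45), 240, 65)
  sd_obs <- sd(a$data[lab$data == 1])
  expect_equal(sd_obs, 0.05 * mu, tolerance = 0.15)
})

test_that("rigid resampling is exact on grid-aligned moves and invertible", {
  lab <- small_labels()
  img <- synthesize_suv_volume(lab, uniform_kinetics(lab, kinetic_params()),
                               feng_input(), 240, 65, t = 45, sigma = 0.05,
                               seed = 3)
  # identity
  expect_identical(apply_rigid(img)$data, img$data)
  # one-voxel translation along x shifts the array by one index
  sh <- apply_rigid(img, translation = c(img$affine[1, 1], 0, 0))
  d <- dim(img$data)
  expect_equal(sh$data[2:d[1], , ], img$data[1:(d[1] - 1), , ], tolerance = 1e-10)
  # rotation round trip within interpolation tolerance (smooth field: the
  # trilinear error bound presumes band-limited data, not step edges)
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  r2 <- (grid$i - d[1] / 2)^2 + (grid$j - d[2] / 2)^2 + (grid$k - d[3] / 2)^2
  smooth <- new_suv_volume(array(6 * exp(-r2 / 60), dim = d), img$affine,
                           t_min = 45)
  rot <- apply_rigid(apply_rigid(smooth, rotation = c(0, 0, 7)),
                     rotation = c(0, 0, -7))
  rng <- diff(range(smooth$data))
  interior <- array(FALSE, d)
  interior[3:(d[1] - 2), 3:(d[2] - 2), 3:(d[3] - 2)] <- TRUE
  expect_lt(max(abs(rot$data[interior] - smooth$data[interior])), 0.02 * rng)
  expect_error(apply_rigid(img, translation = c(NA, 0, 0)),
               class = "dtpet_geometry_error")
})

test_that("cohort simulation is deterministic and follows its sampling laws", {
  cfg <- cohort_config(n = 2, shape = c(24, 24, 20), n_regions = 2)
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_identical(a$scans, b$scans)
  expect_identical(a$volumes[[1]]$early$data, b$volumes[[1]]$early$data)
  expect_identical(a$regional, b$regional)
  # identical NIfTI bytes for identical config + seed
  f1 <- tempfile(fileext = ".nii.gz"); f2 <- tempfile(fileext = ".nii.gz")
  write_volume(a$volumes[[1]]$early, f1)
  write_volume(b$volumes[[1]]$early, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(simulate_cohort(cohort_config(n = 1)), class = "dtpet_config_error")

  # scan times respect the truncation windows; dose follows the per-kg rule
  coh <- simulate_cohort(regional_config(n = 52), seed = 9)
  expect_true(all(coh$scans$t_early_min >= 20 & coh$scans$t_early_min <= 90))
  expect_true(all(coh$scans$t_delayed_min >= 120 & coh$scans$t_delayed_min <= 200))
  expect_equal(coh$scans$dose_MBq, round(3.7 * coh$scans$weight_kg, 1))
  expect_true(all(coh$scans$t_early_min < coh$scans$t_delayed_min))
})

test_that("MRI-positive counts follow the binomial design proportion", {
  cfg <- regional_config(n = 52, noise_sigma = 0, heterogeneity_sdlog = 0,
                         t_early = list(sd = 0), t_delayed = list(sd = 0),
                         weight = list(sd = 0))
  counts <- vapply(seq_len(200), function(s) {
    coh <- simulate_cohort(cfg, seed = 1000 + s)
    sum(coh$scans$mri_status == "positive")
  }, numeric(1))
  expect_gte(mean(counts), 30)
  expect_lte(mean(counts), 38)
})

test_that("zero randomness collapses the cohort to identical AI records", {
  cfg <- regional_config(n = 4, noise_sigma = 0, heterogeneity_sdlog = 0,
                         t_early = list(sd = 0), t_delayed = list(sd = 0),
                         weight = list(sd = 0))
  rec <- ai_records(simulate_cohort(cfg, seed = 3))
  expect_equal(length(unique(round(rec$ai1, 12))), 1)
  expect_equal(length(unique(round(rec$ai2, 12))), 1)
})

test_that("symmetric noise-free phantoms have zero asymmetry everywhere", {
  lab <- small_labels()
  img <- synthesize_suv_volume(lab, uniform_kinetics(lab, kinetic_params()),
                               feng_input(), 240, 65, t = 45)
  for (r in seq_len(nrow(lab$pairs))) {
    p <- paired_suvmeans(img, lab, lab$pairs$lh_label[r])
    expect_lt(abs(asymmetry_index(p$suv_ez, p$suv_contra)), 1e-9)
  }
})

test_that("cohort-mean AI under default noise stays near the noise-free AI", {
  cfg <- regional_config(n = 52, noise_sigma = 0.05, heterogeneity_sdlog = 0,
                         t_early = list(sd = 0), t_delayed = list(sd = 0),
                         weight = list(sd = 0))
  cfg0 <- regional_config(n = 2, noise_sigma = 0, heterogeneity_sdlog = 0,
                          t_early = list(sd = 0), t_delayed = list(sd = 0),
                          weight = list(sd = 0))
  noise_free <- ai_records(simulate_cohort(cfg0, seed = 1))
  means <- vapply(seq_len(200), function(s) {
    rec <- ai_records(simulate_cohort(cfg, seed = 5000 + s))
    c(mean(rec$ai1), mean(rec$ai2))
  }, numeric(2))
  expect_lt(abs(mean(means[1, ]) - noise_free$ai1[1]), 1)
  expect_lt(abs(mean(means[2, ]) - noise_free$ai2[1]), 1)
})
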