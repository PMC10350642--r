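#' Specification of a synthetic parcellated brain phantom
#'
#' The phantom is a left/right-symmetric ellipsoidal "brain" split at the
#' mid-sagittal (world x = 0) plane, each hemisphere subdivided into angular
#' wedge regions named in DKT atlas style (`lh_roi_*` / `rh_roi_*`). It stands
#' in for patient anatomy plus an MRI segmentation, preserving the only
#' structure the asymmetry analysis needs: paired left/right cortical ROIs.
#'
#' @param shape Grid dimensions in voxels (length 3, each `>= 16`); the first
#'   (x) dimension should be even so the midline falls between voxel columns.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param n_regions Paired cortical regions per hemisphere (`>= 1`).
#' @param ez_region Index (1..n_regions) of the region hosting the
#'   epileptogenic zone.
#' @param noise_sigma Gaussian image noise as a fraction of the regional mean.
#' @param rigid_mm,rigid_deg Magnitude of optional rigid perturbation applied
#'   to synthesized volumes (0 disables).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 48), voxel_mm = 3, n_regions = 8,
                         ez_region = 1, noise_sigma = 0.05,
                         rigid_mm = 0, rigid_deg = 0) {
  if (length(shape) != 3 || any(shape < 16)) {
    stop_dtpet("Phantom grid must be 3-D with every dimension >= 16.",
               "dtpet_spec_error")
  }
  if (n_regions < 1) stop_dtpet("n_regions must be >= 1.", "dtpet_spec_error")
  if (noise_sigma < 0) stop_dtpet("noise_sigma must be >= 0.", "dtpet_spec_error")
  if (ez_region < 1 || ez_region > n_regions) {
    stop_dtpet("ez_region must index one of the n_regions wedges.", "dtpet_spec_error")
  }
  structure(list(shape = as.integer(shape), voxel_mm = voxel_mm,
                 n_regions = as.integer(n_regions),
                 ez_region = as.integer(ez_region),
                 noise_sigma = noise_sigma,
                 rigid_mm = rigid_mm, rigid_deg = rigid_deg),
            class = "phantom_spec")
}

# Centered affine: world = (idx - (dim+1)/2) * voxel, RAS axes. For an even
# x-dimension the midline x = 0 falls exactly between two voxel columns, so
# the phantom mirrors voxel-for-voxel (i <-> nx+1-i).
centered_affine <- function(shape, voxel_mm) {
  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * (shape + 1) / 2
  aff
}

# Right-hemisphere labels are offset by 100 from their left partners.
RH_OFFSET <- 100L

#' Build the symmetric parcellated label volume
#'
#' Voxel centers inside an ellipsoid spanning ~92% of the grid are brain;
#' the world x sign selects the hemisphere (RAS: +x is right) and the angular
#' position in the (y, z) plane selects one of `n_regions` wedges per
#' hemisphere. Left-hemisphere wedge `k` gets label `k`, its right mirror
#' label `100 + k`. Voxels exactly on x = 0 (odd x-dimension only) stay
#' background so the two hemispheres are exact mirrors.
#'
#' @param spec A [phantom_spec()].
#' @return A `label_volume` with a populated pairing table.
#' @examples
#' lab <- build_labels(phantom_spec(shape = c(24, 24, 20), n_regions = 2))
#' lab$pairs
#' @export
build_labels <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  aff <- centered_affine(d, spec$voxel_mm)
  x <- (seq_len(d[1]) - (d[1] + 1) / 2) * spec$voxel_mm
  y <- (seq_len(d[2]) - (d[2] + 1) / 2) * spec$voxel_mm
  z <- (seq_len(d[3]) - (d[3] + 1) / 2) * spec$voxel_mm
  semi <- 0.92 * d * spec$voxel_mm / 2
  X <- array(rep(x, times = d[2] * d[3]), dim = d)
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), dim = d)
  Z <- array(rep(z, each = d[1] * d[2]), dim = d)
  inside <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
  theta <- atan2(Z, Y)  # (-pi, pi], symmetric in x by construction
  wedge <- array(pmin(as.integer(floor((theta + pi) / (2 * pi / spec$n_regions))) + 1L,
                      spec$n_regions), dim = d)
  lab <- array(0L, dim = d)
  lab[inside & X < 0] <- wedge[inside & X < 0]
  lab[inside & X > 0] <- wedge[inside & X > 0] + RH_OFFSET
  counts <- table(lab[lab > 0])
  expected <- c(seq_len(spec$n_regions), seq_len(spec$n_regions) + RH_OFFSET)
  if (!all(as.character(expected) %in% names(counts)) || any(counts < 20)) {
    stop_dtpet(paste0(
      "Region count too large for this grid: every region needs >= 20 voxels ",
      "(smallest has ", if (length(counts)) min(counts) else 0, ")."
    ), "dtpet_spec_error")
  }
  pairs <- tibble(
    region = seq_len(spec$n_regions),
    lh_label = seq_len(spec$n_regions),
    rh_label = seq_len(spec$n_regions) + RH_OFFSET,
    lh_name = sprintf("lh_roi_%d", seq_len(spec$n_regions)),
    rh_name = sprintf("rh_roi_%d", seq_len(spec$n_regions))
  )
  new_label_volume(lab, aff, pairs, voxel_mm = spec$voxel_mm)
}

# Mirror partner of a label via the pairing table.
mirror_label <- function(labels, label) {
  p <- labels$pairs
  out <- integer(length(label))
  is_lh <- label %in% p$lh_label
  is_rh <- label %in% p$rh_label
  if (!all(is_lh | is_rh)) {
    stop_dtpet(sprintf("Label(s) %s not in the pairing table.",
                       paste(label[!(is_lh | is_rh)], collapse = ", ")),
               "dtpet_pairing_error")
  }
  out[is_lh] <- p$rh_label[match(label[is_lh], p$lh_label)]
  out[is_rh] <- p$lh_label[match(label[is_rh], p$rh_label)]
  out
}

label_name <- function(labels, label) {
  p <- labels$pairs
  nm <- character(length(label))
  is_lh <- label %in% p$lh_label
  nm[is_lh] <- p$lh_name[match(label[is_lh], p$lh_label)]
  nm[!is_lh] <- p$rh_name[match(label[!is_lh], p$rh_label)]
  nm
}

#' Synthesize an SUV volume from regional kinetics
#'
#' Each region's noise-free voxel value is the SUV predicted by the
#' two-tissue-compartment model for its rate constants at acquisition time
#' `t`; Gaussian noise with per-region standard deviation
#' `sigma * regional mean` is then added voxelwise (draws clipped at -5
#' standard deviations). Background stays 0.
#'
#' @param labels A `label_volume`.
#' @param regional_kinetics Named list mapping label (as character) to
#'   [kinetic_params()]; every non-background label must be present.
#' @param input A plasma input object.
#' @param dose_MBq,weight_kg Scan dose and body weight for the SUV scale.
#' @param t Acquisition time post-injection (min).
#' @param sigma Noise fraction of the regional mean (default 0 = noise-free).
#' @param seed Optional seed for the noise draws (restores the caller's RNG
#'   state afterwards).
#' @return An `suv_volume`.
#' @export
synthesize_suv_volume <- function(labels, regional_kinetics, input,
                                  dose_MBq, weight_kg, t,
                                  sigma = 0, seed = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  lab_ids <- sort(unique(as.integer(labels$data[labels$data > 0])))
  missing <- setdiff(as.character(lab_ids), names(regional_kinetics))
  if (length(missing)) {
    stop_dtpet(paste0("Missing kinetics for label(s): ",
                      paste(missing, collapse = ", ")),
               "dtpet_config_error")
  }
  # Deduplicate identical parameter sets so the quadrature runs once per
  # distinct (K1, k2, k3) triple, not once per region.
  key <- vapply(regional_kinetics[as.character(lab_ids)], function(kp)
    paste(kp$K1, kp$k2, kp$k3, sep = "|"), character(1))
  uniq <- !duplicated(key)
  act <- vapply(regional_kinetics[as.character(lab_ids)][uniq], function(kp)
    tissue_activity(kp, input, t), numeric(1))
  suv0 <- suv_from_activity(act[match(key, key[uniq])], dose_MBq, weight_kg)
  names(suv0) <- as.character(lab_ids)

  vol <- array(0, dim = dim(labels$data))
  idx_by_label <- split(seq_along(labels$data), as.integer(labels$data))
  idx_by_label[["0"]] <- NULL
  fill <- function() {
    for (lid in names(idx_by_label)) {
      idx <- idx_by_label[[lid]]
      mu <- suv0[[lid]]
      if (sigma > 0) {
        noise <- pmax(rnorm(length(idx), 0, sigma * mu), -5 * sigma * mu)
        vol[idx] <<- mu + noise
      } else {
        vol[idx] <<- mu
      }
    }
  }
  if (sigma > 0) with_seed_(seed, fill()) else fill()
  new_suv_volume(vol, labels$affine, t_min = t, dose_MBq = dose_MBq,
                 weight_kg = weight_kg)
}
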