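# Shared fixtures: small phantoms and inputs built in code at test time.

small_spec <- function(...) {
  phantom_spec(shape = c(24, 24, 20), voxel_mm = 3, n_regions = 2, ...)
}

small_labels <- function(...) build_labels(small_spec(...))

# Constant plasma input c over [0, t_max] realized as a tabulated function.
const_input <- function(value = 10, t_max = 1000) {
  tabulated_input(c(0, t_max), c(value, value))
}

# Kinetics map giving every label in `labels` the same parameters, with an
# optional override for one label.
uniform_kinetics <- function(labels, kp = kinetic_params(),
                             override_label = NULL, override_kp = NULL) {
  ids <- sort(unique(as.integer(labels$data[labels$data > 0])))
  kin <- stats::setNames(rep(list(kp), length(ids)), as.character(ids))
  if (!is.null(override_label)) kin[[as.character(override_label)]] <- override_kp
  kin
}

# Independent ODE oracle for the two-tissue-compartment model (deSolve),
# kept out of the implementation path on purpose.
ode_tissue_activity <- function(kp, input, t) {
  rhs <- function(tt, y, parms) {
    cp <- plasma_concentration(input, tt, warn_extrapolation = FALSE)
    list(c(kp$K1 * cp - (kp$k2 + kp$k3) * y[1], kp$k3 * y[1]))
  }
  out <- deSolve::lsoda(c(C1 = 0, C2 = 0), c(0, t), rhs, NULL,
                        rtol = 1e-9, atol = 1e-12)
  sum(out[nrow(out), c("C1", "C2")])
}

# Fast regional-mode configuration for replicate studies.
regional_config <- function(...) {
  cohort_config(mode = "regional", shape = c(16, 16, 16), n_regions = 1,
                ez_region = 1, ...)
}
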