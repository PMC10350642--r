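#' Feng-form arterial plasma input function
#'
#' Builds a tri-exponential plasma time-activity model of the form
#' \deqn{C_p(t) = (A_1 t - A_2 - A_3)e^{\lambda_1 t} + A_2 e^{\lambda_2 t} +
#'   A_3 e^{\lambda_3 t}}
#' which starts at zero activity at injection, rises sharply through a bolus
#' peak and decays with slow washout — the standard parametric description of
#' an FDG arterial input. The default coefficients are generic literature-style
#' adult FDG values (kBq/mL scale); they are calibration choices, not
#' measurements, and should be overridden when a measured input is available.
#'
#' @param A1 Bolus slope coefficient (kBq mL^-1 min^-1).
#' @param A2,A3 Washout amplitudes (kBq/mL).
#' @param l1,l2,l3 Eigenvalues (min^-1); all must be negative.
#' @return An object of class `c("feng_input", "plasma_input")`.
#' @examples
#' cp <- feng_input()
#' plasma_concentration(cp, c(0, 1, 45, 160))
#' @export
feng_input <- function(A1 = 851.1, A2 = 21.9, A3 = 20.8,
                       l1 = -4.134, l2 = -0.1191, l3 = -0.0104) {
  vals <- c(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3)
  if (!all(is.finite(vals))) {
    stop_dtpet("All Feng input coefficients must be finite.", "dtpet_input_error")
  }
  if (any(c(l1, l2, l3) >= 0)) {
    stop_dtpet("Feng eigenvalues l1, l2, l3 must all be negative.", "dtpet_input_error")
  }
  if (any(c(A1, A2, A3) < 0)) {
    stop_dtpet("Feng amplitudes A1, A2, A3 must be non-negative.", "dtpet_input_error")
  }
  structure(list(A1 = A1, A2 = A2, A3 = A3, l1 = l1, l2 = l2, l3 = l3),
            class = c("feng_input", "plasma_input"))
}

#' Tabulated plasma input function
#'
#' Wraps measured (time, concentration) samples; evaluation interpolates
#' linearly between samples and returns zero outside the sampled interval
#' (with a warning beyond the last sample).
#'
#' @param times Sample times (min), strictly increasing, first sample at 0.
#' @param concentrations Plasma activity concentrations (kBq/mL), non-negative.
#' @return An object of class `c("tabulated_input", "plasma_input")`.
#' @export
tabulated_input <- function(times, concentrations) {
  if (length(times) != length(concentrations) || length(times) < 2) {
    stop_dtpet("Need at least two (time, concentration) samples of equal length.",
               "dtpet_input_error")
  }
  if (any(diff(times) <= 0)) {
    stop_dtpet("Tabulated times must be strictly increasing.", "dtpet_input_error")
  }
  if (times[1] != 0) {
    stop_dtpet("Tabulated input must start at t = 0.", "dtpet_input_error")
  }
  if (any(concentrations < 0)) {
    stop_dtpet("Tabulated concentrations must be non-negative.", "dtpet_input_error")
  }
  structure(list(times = as.numeric(times), conc = as.numeric(concentrations)),
            class = c("tabulated_input", "plasma_input"))
}

#' Evaluate a plasma input function
#'
#' @param input A [feng_input()] or [tabulated_input()] object.
#' @param t Time(s) post-injection (min); must be non-negative.
#' @param warn_extrapolation Warn when a tabulated input is evaluated beyond
#'   its last sample (where it returns 0).
#' @return Plasma activity concentration(s) Cp(t) in kBq/mL.
#' @export
plasma_concentration <- function(input, t, warn_extrapolation = TRUE) {
  UseMethod("plasma_concentration")
}

#' @export
plasma_concentration.feng_input <- function(input, t, warn_extrapolation = TRUE) {
  if (any(t < 0)) stop_dtpet("Plasma input requires t >= 0.", "dtpet_domain_error")
  val <- with(input, (A1 * t - A2 - A3) * exp(l1 * t) + A2 * exp(l2 * t) + A3 * exp(l3 * t))
  pmax(val, 0)  # physical concentration; also absorbs roundoff at t = 0
}

#' @export
plasma_concentration.tabulated_input <- function(input, t, warn_extrapolation = TRUE) {
  if (any(t < 0)) stop_dtpet("Plasma input requires t >= 0.", "dtpet_domain_error")
  beyond <- t > input$times[length(input$times)]
  if (any(beyond) && warn_extrapolation) {
    warn(sprintf(
      "%d time point(s) beyond the last tabulated sample (%.6g min); returning 0 there.",
      sum(beyond), input$times[length(input$times)]
    ))
  }
  out <- approx(input$times, input$conc, xout = t, method = "linear",
                yleft = 0, yright = 0)$y
  out
}

#' Irreversible two-tissue-compartment rate constants
#'
#' The Sokoloff description of cerebral FDG kinetics: plasma-to-tissue
#' transport `K1` (mL min^-1 g^-1), tissue-to-plasma efflux `k2` (min^-1) and
#' hexokinase phosphorylation `k3` (min^-1). Dephosphorylation `k4` is fixed at
#' zero (irreversible trapping), appropriate for scans within ~3 h of
#' injection. Defaults are typical published adult gray-matter FDG values and
#' are intended as simulation baselines, not subject estimates.
#'
#' @param K1 Transport rate (mL min^-1 g^-1), `>= 0`.
#' @param k2 Efflux rate (min^-1), `>= 0`.
#' @param k3 Phosphorylation rate (min^-1), `>= 0`.
#' @return An object of class `"kinetic_params"` (k4 is fixed at 0).
#' @examples
#' kp <- kinetic_params()
#' patlak_ki(kp)
#' @export
kinetic_params <- function(K1 = 0.102, k2 = 0.130, k3 = 0.062) {
  vals <- c(K1 = K1, k2 = k2, k3 = k3)
  if (!all(is.finite(vals)) || any(vals < 0)) {
    stop_dtpet("K1, k2, k3 must be finite and non-negative.", "dtpet_parameter_error")
  }
  if (k3 > 0 && k2 + k3 <= 0) {
    stop_dtpet("k2 + k3 must be positive when k3 > 0.", "dtpet_parameter_error")
  }
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = 0), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "Two-tissue-compartment FDG kinetics (irreversible)\n  K1 = %.4g mL/min/g, k2 = %.4g /min, k3 = %.4g /min, k4 = 0\n  Ki = %.4g mL/min/g\n",
    x$K1, x$k2, x$k3, if (x$k2 + x$k3 > 0) x$K1 * x$k3 / (x$k2 + x$k3) else 0
  ))
  invisible(x)
}

#' Patlak net influx rate
#'
#' `Ki = K1 * k3 / (k2 + k3)`, the net FDG trapping rate that governs the
#' late-time uptake slope; `0 <= Ki <= K1`.
#'
#' @param kp A [kinetic_params()] object.
#' @return Influx rate Ki (mL min^-1 g^-1).
#' @export
patlak_ki <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (kp$k2 + kp$k3 <= 0) {
    stop_dtpet("Patlak Ki undefined: k2 + k3 must be positive.", "dtpet_parameter_error")
  }
  kp$K1 * kp$k3 / (kp$k2 + kp$k3)
}

#' Tissue activity concentration under the irreversible 2TC model
#'
#' Solves the compartment system
#' \deqn{dC_1/dt = K_1 C_p(t) - (k_2+k_3) C_1, \quad dC_2/dt = k_3 C_1}
#' with zero initial conditions and returns total tissue activity
#' `Ct = C1 + C2`. The solution is evaluated through its integral form
#' \deqn{C_t(t) = K_i \int_0^t C_p \, ds +
#'       \frac{K_1 k_2}{k_2+k_3} \int_0^t e^{-(k_2+k_3)(t-s)} C_p(s) \, ds}
#' by adaptive quadrature (absolute tolerance 1e-6 kBq/mL), which keeps the
#' core free of an ODE-solver dependency. A tissue density of 1 g/mL is
#' assumed so per-gram rate constants yield per-mL activities.
#'
#' @param kp A [kinetic_params()] object.
#' @param input A plasma input object.
#' @param t Time(s) post-injection (min), `>= 0`.
#' @return Tissue activity concentration(s) Ct(t) in kBq/mL.
#' @examples
#' tissue_activity(kinetic_params(), feng_input(), c(43.44, 160.46))
#' @export
tissue_activity <- function(kp, input, t) {
  stopifnot(inherits(kp, "kinetic_params"), inherits(input, "plasma_input"))
  if (any(t < 0)) stop_dtpet("tissue_activity requires t >= 0.", "dtpet_domain_error")
  alpha <- kp$k2 + kp$k3
  if (alpha <= 0 && kp$k3 > 0) {
    stop_dtpet("k2 + k3 = 0 with k3 > 0 is not a valid parameterization.",
               "dtpet_parameter_error")
  }
  cp <- function(s) plasma_concentration(input, s, warn_extrapolation = FALSE)
  vapply(t, function(tt) {
    if (tt == 0 || kp$K1 == 0) return(0)
    i0 <- integrate(cp, 0, tt, rel.tol = 1e-9, abs.tol = 1e-6,
                    subdivisions = 500L)$value
    if (alpha <= 0) return(kp$K1 * i0)  # pure accumulation, k2 = k3 = 0
    iconv <- integrate(function(s) exp(-alpha * (tt - s)) * cp(s),
                       0, tt, rel.tol = 1e-9, abs.tol = 1e-6,
                       subdivisions = 500L)$value
    kp$K1 * kp$k3 / alpha * i0 + kp$K1 * kp$k2 / alpha * iconv
  }, numeric(1))
}

#' Standardized uptake value from activity concentration
#'
#' `SUV = Ct [kBq/mL] * body weight [g] / injected dose [kBq]`
#' (dimensionless under 1 g/mL tissue density). Activities are treated as
#' already decay-corrected to injection time, the usual scanner convention;
#' SUV can therefore rise between an early and a delayed scan as tracer
#' continues to accumulate.
#'
#' @param activity Activity concentration(s) (kBq/mL).
#' @param dose_MBq Injected dose (MBq), `> 0`.
#' @param weight_kg Body weight (kg), `> 0`.
#' @return SUV value(s), dimensionless.
#' @examples
#' suv_from_activity(5, dose_MBq = 3.7 * 70, weight_kg = 70)
#' @export
suv_from_activity <- function(activity, dose_MBq, weight_kg) {
  if (!is.finite(dose_MBq) || dose_MBq <= 0) {
    stop_dtpet("Injected dose must be positive.", "dtpet_domain_error")
  }
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop_dtpet("Body weight must be positive.", "dtpet_domain_error")
  }
  # (weight_kg * 1000 g) / (dose_MBq * 1000 kBq) == weight_kg / dose_MBq
  activity * weight_kg / dose_MBq
}

#' Simulated time-activity curve as a tidy table
#'
#' Evaluates plasma and tissue activity over a time grid and converts to SUV,
#' returning one row per time point — convenient for plotting or CSV export.
#'
#' @inheritParams tissue_activity
#' @param times Evaluation times (min).
#' @param dose_MBq,weight_kg Dose and weight used for the SUV scale.
#' @return A tibble with columns `t_min`, `cp_kbq_ml`, `ct_kbq_ml`, `suv`,
#'   classed `"fdg_tac"` for [ggplot2::autoplot()].
#' @export
tissue_curve <- function(kp, input, times = seq(0, 180, by = 2),
                         dose_MBq = 3.7 * 65, weight_kg = 65) {
  out <- tibble(
    t_min = times,
    cp_kbq_ml = plasma_concentration(input, times, warn_extrapolation = FALSE),
    ct_kbq_ml = tissue_activity(kp, input, times),
    suv = suv_from_activity(ct_kbq_ml, dose_MBq, weight_kg)
  )
  class(out) <- c("fdg_tac", class(out))
  out
}
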