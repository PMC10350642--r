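---
title: "Dual-time-point FDG-PET asymmetry: models, phantom design and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-time-point FDG-PET asymmetry: models, phantom design and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtpet)
```

## The problem

In temporal lobe epilepsy, the epileptogenic zone (EZ) is interictally
hypometabolic on ¹⁸F-FDG PET. Dual-time-point imaging acquires two static
scans from one injection — early (~40 min) and delayed (~2–3 h) — and asks
whether the left/right asymmetry of the EZ becomes more conspicuous on the
delayed scan. `dtpet` provides (i) the quantification: regional SUVmean
extraction, the asymmetry index, cohort statistics and inter-rater
agreement; and (ii) a kinetic phantom that generates whole synthetic
cohorts, because patient images for this design are generally not shared.
The phantom is not decoration: it is the package's testbed, letting every
statistical property be checked against a known ground truth.

## Kinetic model

Tissue FDG follows the irreversible two-tissue-compartment (Sokoloff) model:
free tracer $C_1$ exchanges with plasma ($K_1$ in, $k_2$ out) and is
phosphorylated at rate $k_3$ into trapped FDG-6-P ($C_2$); dephosphorylation
$k_4$ is fixed at 0, the standard approximation for brain scans within ~3 h.
Total tissue activity is evaluated through the integral form

$$C_t(t) = K_i \int_0^t C_p\,ds \;+\;
  \frac{K_1 k_2}{k_2+k_3} \int_0^t e^{-(k_2+k_3)(t-s)} C_p(s)\,ds,
  \qquad K_i = \frac{K_1 k_3}{k_2+k_3},$$

by adaptive quadrature (absolute tolerance $10^{-6}$ kBq/mL, relative
$10^{-9}$). We deliberately avoid an ODE solver in the core — the quadrature
of the closed-form convolution is faster and has one fewer dependency — and
keep `deSolve` as the *test oracle only*: the suite checks agreement to a
relative $10^{-3}$ over a parameter grid that includes the degenerate edges
$k_3 = 0$ (reversible single compartment) and $k_2 = 0$ ($K_i = K_1$). When
$k_2 = k_3 = 0$ the expression degenerates to pure accumulation
$K_1\int C_p$, handled explicitly.

The plasma input is the Feng tri-exponential
$C_p(t) = (A_1 t - A_2 - A_3)e^{\lambda_1 t} + A_2 e^{\lambda_2 t} + A_3 e^{\lambda_3 t}$,
which is zero at injection by construction; defaults
($A_1 = 851.1$ kBq mL⁻¹ min⁻¹, $A_2 = 21.9$, $A_3 = 20.8$ kBq/mL,
$\lambda = -4.134, -0.1191, -0.0104$ min⁻¹) are generic literature-style
adult values — they are *calibration choices, not measurements*, and every
coefficient is a config key. Tiny negative excursions from floating-point
cancellation at $t = 0$ are clamped to zero. A tabulated input mode
(linear interpolation, zero outside the samples, warning beyond the last
sample) accepts measured curves.

SUV uses the community convention
$\mathrm{SUV} = C_t\,[\mathrm{kBq/mL}] \times \mathrm{weight}\,[\mathrm{g}] /
\mathrm{dose}\,[\mathrm{kBq}]$ with tissue density 1 g/mL reconciling
per-gram rate constants with per-mL image units. Simulated activities are
treated as decay-corrected to injection time (standard scanner behavior), so
SUV keeps rising between the two scans as tracer accumulates — which is why
both regions brighten on delayed imaging while their *asymmetry* grows.

One modeling question was genuinely open: kinetic studies of epileptic
hypometabolism have been read as suggesting $k_3$ increases at delayed
times. We implement a time-constant $k_3$ — the canonical model — and treat
any time-varying extension as out of scope rather than guessing its form.

## Phantom design

The phantom is a left/right-symmetric ellipsoid on a configurable grid
(default $64\times64\times48$ voxels at 3 mm), split at the mid-sagittal
world plane $x = 0$ and subdivided into angular wedges — by default 8 paired
cortical regions per hemisphere, named `lh_roi_*`/`rh_roi_*` in the style of
standard parcellations. A real atlas has ~100 regions; 8 keeps runtimes
desk-scale while preserving the only structure the analysis needs, the
left/right pairing. Geometry conventions: 1-based voxel indices, RAS world
axes, NIfTI-style affines; with an even x-dimension the midline falls
between voxel columns, so mirror symmetry is exact voxel-for-voxel (the test
suite asserts that flipping the label array equals swapping lh/rh labels).

Per-voxel noise is Gaussian with regional standard deviation
$\sigma \times$ (regional mean), default $\sigma = 5\%$ — simple, and enough
to exercise the statistics; reconstruction (Poisson-like, spatially
correlated) noise is out of scope. Draws are clipped at $-5\sigma$ so noisy
SUV cannot go meaningfully negative.

A cohort (default $n = 52$) samples per patient: weight from
Normal(65, 12²) kg truncated to [30, 110] (weights are needed only to
realize the 3.7 MBq/kg dose rule; the protocol itself specifies no
weights); early scan time from Normal(43.44, 18.04²) min truncated to
[20, 90] and delayed from Normal(160.46, 28.70²) truncated to [120, 200]
(truncation keeps the samples inside the protocol windows of roughly 40 min
and 2–3 h); EZ side left with probability 0.5; MRI-positive with
probability 34/52; and lognormal kinetic heterogeneity (sdlog 0.1 on
$K_1, k_2, k_3$, shared by both hemispheres so that asymmetry comes only
from the EZ). The EZ itself multiplies $K_1$ by 0.92 and $k_3$ by 0.75.
Under these defaults the noise-free phantom gives AI1 ≈ 22 and AI2 ≈ 27;
absolute AI and SUV levels are calibration choices — no images or
per-patient values exist to reproduce — and what the phantom is built to
carry is the *mechanism*: lower EZ $K_i$ makes asymmetry strictly grow with
time, which the suite verifies over a full parameter grid and at cohort
scale (mean ΔAI > 0, paired-t p < 0.05, in ≥ 95% of 200 seeded replicates).

Two cohort modes exist. `"voxel"` synthesizes full NIfTI volumes and is the
default. `"regional"` draws regional SUVmeans directly with noise sd
$\sigma \mu / \sqrt{n_\mathrm{voxels}}$ — exactly the sampling distribution
of a regional mean under the voxel noise model — and is used for
replicate-heavy studies (a 52-patient cohort in well under a second). The
equivalence of the two modes is itself a test: voxel-mode regional means
are checked to follow the regional draw law in both location and spread.

What passing tests on this phantom do **not** show: performance on real
anatomy (partial-volume effects, registration error, heterogeneous
within-region kinetics, reconstruction artifacts are all absent), nor
anything about the clinical accuracy of AI thresholds. They show that the
quantification pipeline is correct and that the kinetic mechanism produces
the dual-time-point effect under controlled conditions.

## Quantification conventions

* Labels are resampled to the PET grid (nearest-neighbour), never PET to
  the label grid — intensities are never interpolated before averaging.
  Half-voxel ties resolve toward the lower index (tested).
* Rigid motion is *applied* (trilinear, zero fill outside the field) for
  phantom perturbation and alignment of known transforms; registration
  estimation is out of scope.
* An EZ may be one region or a named union; a union's SUVmean is
  voxel-weighted (pooled), not a mean of means. Background (label 0) never
  enters any mean.
* AI bands: "10 to 15" is implemented as the closed interval [10, 15] and
  "above 15" as strictly greater — the boundary behavior is a documented
  package convention.
* AI sign: positive = EZ hypometabolic. Patients whose PET lateralization
  opposes the designated EZ side yield negative AI and are retained.
* ΔAI = 0 is reported as its own category, never folded into
  increased/decreased.
* Sample (n−1) SDs everywhere; p-values to 4 significant figures, with
  p < 0.001 never collapsed to literal zero.
* The paired t uses the regularized incomplete beta for its p-value and is
  cross-checked against `stats::t.test` (agreement to 1e-10 in t, 1e-8 in
  p); Cohen's kappa is cross-checked against a brute-force recount from raw
  rating lists. Kappa bands are half-open [lo, hi) with "very good" closed
  at 1.00 (the published scale's endpoints overlap; a convention was
  required). Unanimous identical ratings make kappa undefined (expected
  agreement 1); the pipeline records this rather than failing.

## Observer simulation

Two synthetic readers each perceive a patient's ΔAI plus independent
Normal(0, sd²) perception noise and rate the pair `delayed_better` /
`same` / `early_better` against a symmetric threshold (default 1 AI unit).
With the default phantom's strong, uniform effect (ΔAI ≈ 5) both readers
are often unanimous — kappa is then undefined, which the pipeline reports
explicitly; at larger perception noise kappa is defined and decreases
monotonically with noise, which the suite verifies.

## The packaged clinical table

A 52-patient TLE table (gender, age, video-EEG, MRI, PET and
multidisciplinary EZ localization) ships as a verbatim CSV fixture.
`demographics()` recomputes counts and percentages from the rows — it
reports what the table contains, including a known internal tension: 21
rows carry a literally `Negative` MRI field while the cohort's stated
MRI-negative group is 18, and the published increased-AI percentage
(88.61%) is inconsistent with its own count (44/52 = 84.6%). The fixture is
never "corrected", and all percentages are derived from counts. The cohort
simulator's MRI split uses the stated 34/52 design proportion.

## Problem sizes and runtime

Default test-suite problem sizes were chosen to make the full suite run in
a few minutes on one CPU: phantoms of $24^3$-scale for voxel-level checks,
$16^3$ single-region grids for 200-replicate calibration studies, and the
full default geometry for the mechanism acceptance checks. The acceptance
script runs the complete default 52-patient voxel pipeline plus 200
regional-mode replicate cohorts in under two minutes.

## Known limitations

* No partial-volume correction, attenuation/scatter modeling, or PET
  reconstruction simulation; noise is uncorrelated Gaussian.
* The phantom's anatomy is an ellipsoid; region geometry is wedge-shaped
  and interpatient anatomical variability is not modeled (kinetic
  heterogeneity only).
* The plasma input and gray-matter rate constants are literature-style
  defaults, not fitted to any subject; absolute SUV/AI levels are therefore
  calibration-dependent.
* Only the irreversible model ($k_4 = 0$) is provided; blood-volume terms
  and metabolite corrections are out of scope.
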