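# dtpet — dual-time-point FDG-PET asymmetry analysis for temporal lobe epilepsy

Interictal ¹⁸F-FDG PET shows the epileptogenic zone (EZ) of temporal lobe
epilepsy (TLE) as a region of relative glucose **hypometabolism**. Because
normal cortex keeps trapping FDG faster than epileptogenic cortex, the
left/right metabolic asymmetry **grows** between an early scan (~40 min
post-injection) and a delayed scan (~2–3 h). `dtpet` implements the
quantitative machinery for exploiting that effect — and, since studies of
this design rarely deposit patient images, a fully synthetic cohort engine
that generates dual-time-point SUV volumes from first-principles FDG
kinetics, so every statistical claim in the package is testable end to end.

## The quantities at the core

For a designated EZ region and its mirror region in the opposite hemisphere,
with regional mean standardized uptake values `SUVmean`:

```
AI  = 100 × 2 × (SUVmean_contra − SUVmean_EZ) / (SUVmean_contra + SUVmean_EZ)
ΔAI = AI2 − AI1          (AI1 = early scan, AI2 = delayed scan)
```

`AI > 0` means the EZ side is hypometabolic; AI in [10, 15] is conventionally
*suggestive* of an EZ and AI > 15 *diagnostic*. Cohorts are summarized by
mean ± SD of AI1/AI2/ΔAI (overall and by MRI status) with a paired t-test,
and visual ratings by two readers are scored with Cohen's kappa.

The synthetic engine drives everything with the irreversible
two-tissue-compartment (Sokoloff) model of FDG kinetics,

```
dC1/dt = K1·Cp(t) − (k2 + k3)·C1      dC2/dt = k3·C1      Ct = C1 + C2
```

with a Feng tri-exponential plasma input `Cp`, net influx rate
`Ki = K1·k3/(k2 + k3)`, and SUV = `Ct · weight / dose`. A hypometabolic EZ is
modeled as multiplicative reductions of `K1` and `k3`; because the EZ's `Ki`
is lower, its uptake falls behind the contralateral side ever more as time
passes — the mechanism that makes delayed imaging more asymmetric.

## Worked example

```r
library(dtpet)

# the AI formula on published group-mean SUVs
asymmetry_index(5.21, 5.94)
#> [1] 13.09417
asymmetry_index(5.61, 6.58)
#> [1] 15.91468

# a small synthetic cohort (regional mode skips image synthesis)
cfg <- cohort_config(n = 10, mode = "regional", shape = c(32, 32, 24), n_regions = 4)
coh <- simulate_cohort(cfg, seed = 2026)
rec <- ai_records(coh)
dplyr::select(rec, patient_id, ai1, ai2, dai, band1, band2)
#> # A tibble: 10 x 6
#>   patient_id   ai1   ai2   dai band1      band2
#> 1 sub-001     21.4  28.9  7.44 diagnostic diagnostic
#> 2 sub-002     23.5  27.7  4.20 diagnostic diagnostic
#> ...

glance(summarize_cohort(rec))
#>   stratum     n ai1_mean ai1_sd ai2_mean ai2_sd dai_mean dai_sd n_increased ...
#> 1 all        10     22.2   1.89     27.5  0.780     5.32   1.93          10
```

Every patient's asymmetry increases at the delayed time point (`dai > 0`),
with AI1 ≈ 22 rising to AI2 ≈ 27 under the default phantom kinetics — the
dual-time-point effect the package exists to quantify. Observer simulation
and agreement:

```r
tidy(cohen_kappa(simulate_observers(rec, noise_sd = 3, threshold = 1, seed = 9)))
#>   kappa   p_o   p_e band
#> 1 0.615   0.9  0.74 good agreement
```

The packaged 52-patient clinical table and its demographics:

```r
demographics(load_table1())[, 1:7]
#>      n n_male pct_male age_mean age_sd age_min age_max
#> 1   52     27     51.9     29.5   13.1      10      65
```

For full image-based runs, `run_pipeline(seed = 1, out_dir = "run")` writes
NIfTI volumes, per-patient regional SUVmeans, AI records, the stratified
summary (CSV + JSON), observer ratings with kappa, and a manifest that makes
the run reproducible from config + seed alone. `plot_ai_paired()`,
`plot_delta_ai()` and `autoplot()` methods draw the standard figures.

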