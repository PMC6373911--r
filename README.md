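# cfcpet

Analysis of ramp-incremental cardiopulmonary exercise tests (CPET) in
children and adolescents with cystic fibrosis (CF), built around a
Gaussian-process emulator of the gas-exchange threshold.

## The problem

CPET is part of the routine clinical management of CF: aerobic fitness
predicts hospitalisation and survival, and the gas-exchange threshold
(GET) — the oxygen uptake V̇O₂ at which CO₂ output starts rising
disproportionately as anaerobic pathways engage — is a non-invasive
marker of the anaerobic threshold that correlates well with overall test
performance. Each test is burdensome for young patients, so a
statistical surrogate that predicts the GET from cheaper ventilatory and
spirometric measurements is clinically attractive.

This package implements that analysis chain for researchers in exercise
physiology and biomedical modelling:

1. **Trace handling** — a validated tabular format for breath-by-breath
   traces (time, work rate, V̇O₂, V̇CO₂, V̇E, breathing frequency BF,
   tidal volume V_T, protocol phase markers), with unit normalisation
   and uniform resampling.
2. **Synthetic cohorts** — a seeded generator emulating the ramp
   protocol (3-min warm-up at 10–20 W, ramp at 10–25 W·min⁻¹ to
   exhaustion in ~10 min, 5-min active recovery) with known ground
   truth, standing in for clinical cohorts that cannot be shared.
3. **Feature extraction** — total mechanical energy (the performance
   metric), the log-linear ventilation fit
   log V̇E = α + β·V̇O₂ (first 180 s and last 60 s excluded), V̇O₂ at a
   fixed ventilation of 0.822 L·s⁻¹ (= 49.32 L·min⁻¹), warm-up baseline
   BF and V_T, and the rates of change of BF and V_T.
4. **GET detection** — continuous two-segment (V-slope) least squares of
   V̇CO₂ on V̇O₂ with an exhaustive knot grid and an F-test guard
   against spurious breakpoints.
5. **GP emulation** — Gaussian-process regression with a first-order
   polynomial mean and squared-exponential kernel

   K(x, x′) = σ² ∏ᵢ exp(−|xᵢ − xᵢ′|² / 2Φᵢ²),

   hyperparameters by maximum marginal likelihood, posterior mean and
   variance

   m(z) = μ(z) + K(z,X)ᵀ K(X,X)⁻¹ (y − μ),
   s²(z) = K(z,z) − K(z,X)ᵀ K(X,X)⁻¹ K(z,X),

   and leave-one-out cross-validation
   MSE_LOO = (1/n) Σᵢ (m₋ᵢ(xⁱ) − yᵢ)², with per-patient
   m₋ᵢ ± 1.96 s₋ᵢ intervals. The emulator maps d = 7 inputs (baseline
   BF, baseline V_T, V̇O₂ at fixed V̇E, FVC, FEV₁, BF slope, V_T slope)
   to the GET.
6. **Performance PCA** — principal components of
   (baseline BF, baseline V_T, V̇O₂ at fixed V̇E), the polar angle θ of
   the leading loading against the BF axis, and the fraction of
   total-energy variance explained by the first component.
7. **Mechanistic modelling** — the linear dead-space model
   V̇D = V̇DB + a·W(t) with V̇DB = BF(rest)·V_D(rest) and
   a = BF(ex)·V_D(ex)/W(ex), the alveolar split V̇A = V̇E − V̇D, and a
   compartmental cardiorespiratory ODE core (lung/tissue O₂ and CO₂
   balances, chemoreflex ventilation drive) predicting V̇E from the
   work profile.

## Worked example

```r
library(cfcpet)

cfg <- cohort_config(n_patients = 15, seed = 1)
patient <- generate_patient(cfg, 1)
patient
#> CPET patient record 'P01'
#>   age 17.1 y, FVC 2.42 L, FEV1 1.64 L, ramp 18 W/min
#>   trace: 1078 samples, warm-up 0s, ramp 180s, exhaustion 777.382s, recovery end 1077.38s
#>   ground truth: GET 1.170 L/min at 451s, VO2max 2.220 L/min

detect_get(patient$trace)
#> Gas-exchange threshold (V-slope, two-segment fit, n = 538)
#>   GET = 1.157 L/min at t = 444 s; slopes 0.839 below / 1.367 above
#>   RSS 1.041 (single line 2.901), F-test p = 1.62e-119 -> valid
```

The detected threshold (1.157 L·min⁻¹ at 444 s) recovers the generator's
ground truth (1.170 L·min⁻¹ at 451 s) to about 1% of the ramp V̇O₂
range; the slope above the breakpoint exceeds the slope below, as excess
CO₂ from bicarbonate buffering requires.

```r
features <- cohort_features(generate_cohort(cfg))
gp <- gp_emulator(get_vo2 ~ baseline_bf + baseline_vt + vo2_at_fixed_ve +
                    fvc + fev1 + bf_slope + vt_slope, data = features)
gp_loo(gp, mode = "refit")
#> Leave-one-out cross-validation (refit hyperparameters, n = 15)
#>   MSE_LOO = 0.1358 (12.3% of the mean response)
#>   95% intervals cover 4 / 15 held-out values

pca_performance(features)
#> PCA of (baseline BF, baseline VT, VO2 at fixed VE)
#>   explained variance: 68.9%, 22.8%, 8.2%
#>   theta (first loading vs BF axis) = 0.875 rad
#>   R2 of total energy on PC1 scores = 0.369

deadspace_params(bf_rest = 15, vd_rest = 0.15,
                 bf_ex = 40, vd_ex = 0.20, w_ex = 160)
#> Linear dead-space model: VD(t) = 2.25 + 0.05 * W(t)  [L/min]
```

The leave-one-out error of the emulator on this synthetic 15-patient
cohort is about 12% of the mean threshold — small cohorts of this kind
carry real predictive signal, though the per-fold maximum-likelihood
intervals are overconfident at n = 15 (see the vignette for why, and
for the calibration study under known hyperparameters).

`run_cpet_pipeline()` chains all stages and writes `features.csv`,
`loo_report.csv` (per-patient prediction ± 1.96 s), `gp_model.json`,
`pca.json`, `ventilation_summary.csv` (rest/peak V̇E, V̇D, V̇A per
patient with group means) and a seeded `manifest.json`; identical
configurations reproduce byte-identical bundles.

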