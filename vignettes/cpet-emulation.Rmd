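---
title: "Emulating the gas-exchange threshold from CPET traces: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating the gas-exchange threshold from CPET traces: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfcpet)
```

This vignette is the package's own account of its science: the models
and procedures, their assumptions, the tunable parameters, and the
design choices made where the design was genuinely open.

## 1. The analysis chain

A ramp-incremental cardiopulmonary exercise test (CPET) yields
breath-by-breath time series of oxygen uptake $\dot V O_2$, carbon
dioxide output $\dot V CO_2$, total ventilation $\dot V_E$, breathing
frequency $BF$ and tidal volume $V_T$ under a work profile $W(t)$:
a 3-minute warm-up at a low fixed work rate, a linear ramp chosen to
exhaust the patient in roughly ten minutes, and an active recovery.
The package extracts per-patient physiological descriptors from the
trace, detects the gas-exchange threshold (GET), and fits a
Gaussian-process (GP) regression that predicts the GET from seven
inputs: baseline $BF$, baseline $V_T$, $\dot V O_2$ at a fixed
ventilation, FVC, FEV$_1$, and the rates of change of $BF$ and $V_T$.
Around this core sit a principal-component characterisation of
performance and a mechanistic dead-space/alveolar-ventilation model.

## 2. Trace representation and exclusion windows

Canonical units are L·min$^{-1}$ for flows, L for $V_T$, min$^{-1}$
for $BF$, W for work and s for time; readers convert mL·min$^{-1}$ and
L·s$^{-1}$ dialects explicitly. The validator enforces strictly
increasing time, non-negative channels, ordered phase markers and the
identity $\dot V_E = BF \cdot V_T$ within a configurable relative
tolerance (default 0.1, generous enough for real metabolic-cart noise;
synthetic traces satisfy it exactly).

All regression-type analyses share one window: the first 180 s
(warm-up — work rate not increasing) and the final 60 s before
volitional exhaustion (respiratory compensation induces
hyperventilation and erratic breathing) are excluded. Tests assert the
exclusion exactly: perturbing samples outside the window cannot change
any fitted quantity.

## 3. Feature extraction

* **Total energy** (the performance metric) is the trapezoidal
  integral of $W(t)$ from warm-up start to exhaustion, in kJ. The
  trapezoid rule is exact for the piecewise-linear protocol profiles
  and additive over partitions; no quadrature refinement is needed.
* **Ventilation fit**: ordinary least squares of $\log \dot V_E$ on
  $\dot V O_2$ over the analysis window. Natural logarithms are used —
  the base only rescales intercept and slope jointly, and $e$ is the
  analysis-friendly choice. The inverse of the fitted curve at the
  reference ventilation 0.822 L·s$^{-1}$ = 49.32 L·min$^{-1}$
  (configurable) gives the oxygen-uptake-efficiency input
  $\dot V O_2^{\text{fix}} = (\log \dot V_{E,\text{ref}} - \alpha)/\beta$.
* **Baselines**: arithmetic means of $BF$ and $V_T$ over the warm-up.
* **Slopes**: OLS slopes of $BF$ and $V_T$ against $\dot V O_2$ over
  the same window, mirroring the ventilation-fit convention. Whether
  "rate of change at exercise onset" should be against $\dot V O_2$ or
  against time is ambiguous; both are implemented
  (`ventilatory_slopes(..., against = "time")`), the $\dot V O_2$
  convention is the default, and neither is claimed to be uniquely
  correct.

## 4. Gas-exchange threshold detection

Below the threshold, $\dot V CO_2 \approx RQ \cdot \dot V O_2$; above
it, bicarbonate buffering of lactate adds excess CO$_2$. The detector
fits a *continuous* two-segment piecewise-linear model of
$\dot V CO_2$ on $\dot V O_2$ — segments share the knot point — by
exhaustive search over a knot grid spanning the central 10–90% of the
windowed $\dot V O_2$ range with step 1% of the range (configurable).
A transparent, oracle-checkable formulation was deliberately preferred
over opaque heuristics: tests re-run the search through independent
normal-equation code and assert the global minimum is attained.

Acceptance of the breakpoint uses an F-test (two extra degrees of
freedom: the excess slope and the knot position) at level 0.05 against
the single-line fit, plus the physiological sign condition
slope-above ≥ slope-below. An RSS improvement at rounding-noise level
(relative improvement below $10^{-10}$) is treated as no evidence — a
numerically exact line otherwise produces a spuriously significant F.
The crossing time is the first ramp-phase time at which a 15-s
moving-average $\dot V O_2$ series reaches the threshold; the
smoothing prevents noise-triggered early crossings.

## 5. The Gaussian-process emulator

The emulator assumes GET $= f(\mathbf x)$ with
$f \sim GP(\mu, K)$, first-order polynomial mean
$\mu(\mathbf x) = \beta_0 + \boldsymbol\beta^\top \mathbf x$ and
squared-exponential covariance
$K(\mathbf x, \mathbf x') = \sigma^2 \prod_i
\exp(-|x_i - x_i'|^2 / 2\Phi_i^2)$. Conditioning on training data
gives the posterior mean and variance used for prediction and
uncertainty; at training inputs the posterior interpolates and its
variance collapses to the nugget, far from data it reverts to the
trend and prior variance. Both limits are asserted in tests.

Numerical choices:

* **Standardisation.** Inputs are standardised and the output centred
  and scaled internally (the seven inputs carry incommensurate units,
  so raw lengthscales would be incomparable); predictions are returned
  on the original scale, and an affine-invariance test pins the
  transparency of the transformation.
* **Hyperparameter estimation** maximises the profile log marginal
  likelihood (mean coefficients profiled out by generalised least
  squares) over $\log \sigma, \log \Phi_1..\Phi_d$ with 10 seeded
  multi-start L-BFGS-B runs, each followed by a Nelder–Mead polish —
  the derivative-free step guards against line-search stalls on the
  occasionally kinked profile surface. Box bounds keep lengthscales in
  $[0.05, 50]$ times the input SD. A recovery study (n = 200, d = 1,
  20 replicates) requires the true log-hyperparameters back within
  ±0.5 in at least 90% of runs.
* **Conditioning.** The nugget defaults to $10^{-8}\,\mathrm{var}(y)$
  and escalates tenfold (to at most $10^{-2}\,\mathrm{var}(y)$) on
  Cholesky failure; ill-conditioned covariance matrices are a known
  hazard of near-duplicate training inputs.
* **Predictive variance.** `predict()` reports the plain posterior
  variance by default. The optional `mean_uncertainty = TRUE` adds the
  universal-kriging term
  $u^\top (H^\top K^{-1} H)^{-1} u$, $u = h(z) - H^\top K^{-1} k(z)$,
  accounting for the GLS-estimated mean. Leave-one-out reporting uses
  it by default: with known hyperparameters the resulting predictive
  law is exact, which is what makes the calibration study below clean.

**Leave-one-out cross-validation** reports
$\mathrm{MSE}_{LOO} = \frac1n \sum_i (m_{-i}(\mathbf x^i) - y_i)^2$,
its percentage of the mean response, and the count of
$m_{-i} \pm 1.96\, s_{-i}$ intervals covering the held-out value. Two
modes are provided because the definition of $m_{-i}$ does not fix
whether hyperparameters are re-estimated per fold: `"refit"` (default,
the literal reading) refits everything; `"fixed"` keeps the
hyperparameters and re-estimates only the fold mean — much faster and
exactly calibrated when the hyperparameters are known. Refit-mode
equality with $n$ explicit fit-and-predict runs is asserted to
$10^{-10}$.

**Calibration.** On 50 seeded 15-patient cohorts drawn from a GP with
known hyperparameters, pooled 95%-interval coverage of left-out values
must lie within binomial bounds of 0.95 (it does: the fixed-mode
predictive distribution with the mean-uncertainty term is exact in
this well-specified setting). On realistic synthetic cohorts with
*refit* hyperparameters, coverage falls well below nominal: with
n = 15 and d = 7 the marginal-likelihood surface rewards
near-degenerate explanations (huge lengthscales plus a short one) and
the plug-in variance ignores hyperparameter uncertainty. That
overconfidence is reported honestly rather than patched, and is the
main caveat for small-cohort use of such emulators.

## 6. The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is verified. Protocol
defaults: 15 patients, 180-s warm-up at 15 W, ramp rate derived per
patient so the sampled $\dot VO_{2max}$ is reached in ~600 s (rounded
to whole W·min$^{-1}$ and clipped to the protocol range 10–25), 300-s
recovery at 20 W, 1-s sampling. A test asserts all exhaustion times
fall within ±20% of the 10-minute target.

Physiology, per patient: $\dot V O_2$ follows the work profile through
an optional first-order lag ($\tau$ = 30 s by default; $\tau = 0$
makes the response exactly affine for analytic checks);
$\dot V CO_2$ is piecewise linear in $\dot V O_2$ with slope $RQ$
below the true GET and $RQ$ + excess slope above; $\dot V_E$ is
exponential in $\dot V O_2$, anchored at a sampled resting ventilation
and a sampled peak ventilatory equivalent; a ventilation surge of 25%
builds over the final 60 s before exhaustion so the
respiratory-compensation exclusion rule is testable; $V_T$ rises
saturatingly toward a sampled fraction of FVC (tidal volume is
capacity-limited in CF) and $BF = \dot V_E / V_T$, making the
ventilation identity exact by construction. Noise is additive Gaussian
on $\dot V O_2$/$\dot V CO_2$ (SD 0.03 L·min$^{-1}$) and
multiplicative log-normal on $\dot V_E$ (SD 0.04) — breath-by-breath
variability is proportionally larger in ventilation. Breath timing is
approximated by the uniform 1-s grid rather than simulated breaths;
the analyses operate on resampled grids anyway.

A latent disease-severity factor (standard normal) couples the
parameter draws: more severe disease lowers FVC, FEV$_1$/FVC,
$\dot VO_{2max}$, the GET fraction and the tidal-volume ceiling while
raising the dead-space fraction and the peak ventilatory equivalent.
Without this coupling the seven emulator inputs would be nearly
uninformative about the threshold — unlike any real CF cohort, where
disease severity drives exactly this co-dependence. Loadings are
config-exposed (`severity_loadings`) and chosen once as plausible;
they are not claimed to match any particular cohort.

What the generator does *not* emulate: irregular breath timing,
drift/step artefacts of real metabolic carts, day-to-day within-patient
variability, the supramaximal verification bout, and any longitudinal
disease progression. Passing tests therefore demonstrate correctness
of the algorithms under clean protocol structure plus realistic noise
levels — not robustness to every artefact of clinical data.

Distributional parameters (ages 9–18, FVC around 3 L,
$\dot VO_{2max}$ around 1.9 L·min$^{-1}$, GET at ~55% of
$\dot VO_{2max}$, RQ 0.85, efficiency ~10 mL·min$^{-1}$·W$^{-1}$) are
physiologically plausible textbook-scale values for a paediatric CF
cohort, config-exposed, and not claimed to match any specific study
population.

## 7. Performance PCA

The three variables (baseline $BF$, baseline $V_T$,
$\dot V O_2$ at fixed $\dot V_E$) are standardised before PCA — their
units are incommensurate, so covariance-scale PCA would be dominated
by $BF$. The first loading is sign-normalised to a non-negative $BF$
component; $\theta = \arccos |\ell_1 \cdot \hat e_{BF}|$ expresses it
in spherical-polar form relative to the breathing-frequency axis
(the absolute value makes $\theta \in [0, \pi/2]$ well-defined under
the sign ambiguity of eigenvectors). "Variation in performance
captured" is operationalised as the $R^2$ of regressing total energy
on the first-component scores — one literal, defensible reading of a
quantity whose original definition is ambiguous; it is labelled as
this package's operationalisation.

## 8. Mechanistic dead-space and ODE core

The dead-space algebra is exact arithmetic:
$\dot V_{DB} = BF_{\text{rest}} \cdot V_{D,\text{rest}}$,
$a = BF_{\text{ex}} \cdot V_{D,\text{ex}} / W_{\text{ex}}$,
$\dot V_D(t) = \dot V_{DB} + a W(t)$, $\dot V_A = \dot V_E - \dot V_D$.
Peak-exercise values define the exercise measurement (the alternative,
a mean over exercise, is config-reachable by passing different
measurements); per-patient dead volumes are inputs — for synthetic
patients a dead-space fraction of tidal volume drawn with the severity
factor. Negative $\dot V_A$ is flagged and counted, never clipped: it
signals a mis-parameterised patient.

The ODE core is a compartmental cardiorespiratory model in the
classical steady-state-exercise tradition: lung and tissue mass
balances for O$_2$ and CO$_2$ (states $P_{aO_2}$, $P_{aCO_2}$,
$C_{vO_2}$, $C_{vCO_2}$), algebraic cardiac output
$Q = Q_{\text{rest}} + c_Q \Delta \dot M O_2$ and metabolic rate
$\dot M O_2 = \dot M O_{2,\text{rest}} + \rho W(t)$, a chemoreflex
ventilation drive (central + O$_2$-gated peripheral term) tracked by a
first-order state, and gas exchange driven by
$\dot V_A = \dot V_E - \dot V_D$. Dissociation curves: saturating
exponential for O$_2$, linear for CO$_2$. All parameter values are
documented physiological defaults chosen by this package; the model's
testable surface is its conservation structure (Fick consistency at
equilibrium, integrated O$_2$ flux = consumption + storage change to
0.1%), its exact algebraic steady state (found by root bracketing on
the alveolar-ventilation balance, tolerance $10^{-12}$), and solver
convergence (halving tolerances moves $\dot V_E$ by under 0.1%
sup-norm) — not parameter fidelity to any particular subject.
Integration uses `deSolve::ode` (lsoda, stiff-capable) at relative
tolerance $10^{-8}$.

A known behavioural limitation: with only chemoreflex feedback and no
isocapnic-buffering mechanism, simulated $P_{aCO_2}$ rises further
during heavy exercise than in real subjects, and predicted peak
$\dot V_E$ under-shoots measured values for fit patients. This is the
expected failure mode of steady-state-exercise models of this class
and is part of the motivation for the dead-space extension.

## 9. Reproducibility and problem sizes

Every stochastic component is seeded: cohort generation derives one
sub-seed per patient from `(seed, index)`, the GP multi-start uses its
own `opt_seed`, and sampling functions take explicit seeds; library
code saves and restores the caller's RNG state. The pipeline writes a
manifest (seed, config, versions, config hash) sufficient to
regenerate a byte-identical bundle, and a test asserts it.

The test suite runs cohorts of 5–25 patients, a 100-replicate
threshold-recovery study, a 50-cohort calibration study and a
20-replicate hyperparameter-recovery study at n = 200 — sizes chosen
so the full suite completes in about two minutes on one core while
leaving each statistical check comfortably powered. The acceptance
script runs the complete pipeline at the study's cohort size of 15.

## 10. Known limitations

* The emulator's refit-mode intervals are overconfident at n = 15,
  d = 7 (Section 5); fixed-hyperparameter mode with externally
  justified hyperparameters is the calibrated alternative.
* The V-slope detector assumes a single breakpoint; traces with a
  shallow or double transition yield a valid-but-uncertain knot, and
  the F-test only guards against *no* breakpoint.
* The generator's severity coupling is a modelling convenience for
  realistic co-dependence, not an estimate of CF epidemiology.
* The ODE core is a demonstration-grade integration target for the
  dead-space algebra, not a validated patient-level simulator.
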