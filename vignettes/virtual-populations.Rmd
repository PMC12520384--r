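---
title: "Virtual cardio-respiratory populations and wearable-to-clinical inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual cardio-respiratory populations and wearable-to-clinical inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Consumer wearables measure a handful of bio-signals well — heart rate (HR),
systolic/diastolic blood pressure, arterial O2 saturation (SaO2) — while the
variables clinicians need to monitor cardiovascular and respiratory disease
(central venous pressure CVP, stroke volume SV, cardiac output CO, ejection
fraction EF, arterial gas tensions PaO2 and PaCO2) require invasive or
operator-dependent measurement. This package implements an in-silico
feasibility pipeline for bridging that gap: it generates virtual populations
of healthy and diseased subjects from a closed-loop 0D cardio-respiratory
model, trains one Gaussian-process regressor (GPR) per in-hospital variable
on the wearable-derivable features `x = [HR, CSBP, CDBP, SaO2]`, and
stress-tests the regressors under realistic wearable acquisition errors.

## The reference simulator

The shipped simulator is a reduced closed-loop lumped-parameter model chosen
so that every quantity the pipeline consumes (the nine saved signals and the
twelve extracted indexes) is produced by genuine closed-loop physiology, and
so that the parameters with population-level ranges act through the
mechanisms they name. Downstream modules depend only on the simulate
interface (`simulate_subject(params, config) -> trace`), so a richer model
can be dropped in without changes; `generate_population()` accepts any
`simulator` function.

Structure (15 ODE states, classic fourth-order Runge-Kutta at a fixed step):

* **Circulation** — eight volume compartments: left/right atria and
  ventricles, systemic arteries and veins, pulmonary arteries and veins.
  Vessels are linear compliances; the systemic venous compartment carries
  the unstressed volume `Vu_ven` and total blood volume `Vtot` closes the
  loop (volume is conserved exactly by construction). Ventricles follow the
  time-varying-elastance form: systolic pressure
  `phi(u) * k_sym * Emax * (V - Vu)` blended with an exponential passive
  curve `P0 * (exp(kE * V) - 1)`, with activation
  `phi = sin^2(pi*u/u_sys)` over the systolic fraction of the cycle.
  Valves are non-ideal: forward flow through a small resistance, reverse
  flow through a large but finite one, producing the brief physiological
  backflow at valve closure visible in the aortic flow signal.
* **Heart-period control** — a vagal baroreflex: systemic arterial pressure
  is low-pass filtered, mapped through the sigmoid carotid afferent firing
  curve centred at the activation level `Pn`, then through the efferent
  vagal sigmoid; the target heart period is `T0 + GTv * f_ev`, tracked with
  a 1.5 s effector time constant, plus a small respiratory modulation
  (respiratory sinus arrhythmia).
* **Gas exchange** — alveolar O2/CO2 balances driven by a ventilation
  waveform (4 s respiratory period, chemoreflex gain on PaCO2), a tissue
  compartment with fixed metabolic O2 consumption and CO2 production, and
  Spencer-type dissociation curves: saturation
  `S = X^(1/h) / (K + X^(1/h))` with `X = P (1 + beta P)`, parameterized by
  `hO2`, and CO2 content `Csat_CO2 * X^(1/hCO2) / (kCO2 + X^(1/hCO2))`.
  A small pulmonary shunt mixes venous blood into the arterial side, which
  is what makes SaO2 and PaO2 genuinely sensitive to hemoglobin content.

Baseline values: the 14 range-specified parameters take reference-literature
values where those lie inside the sampling ranges (dissociation-curve
constants `hO2 = 0.3836`, `hCO2 = 1.819`, `kCO2 = 194.4`; ventricular
passive elastances `kE_LV = 0.014`, `kE_RV = 0.011`; `FiO2 = 21%`) and the
midpoint of the range otherwise. The remaining constants were calibrated
once, before any population run, so that the baseline simulation lands
inside the admissible envelope of all twelve indexes; they are documented in
`cr_param_table()`. At baseline the model settles at a mean heart period of
about 0.97 s, MAP 96 mmHg, CVP 3.6 mmHg, EF 64%, SaO2 97.9%, PaO2 96 mmHg
and PaCO2 40 mmHg.

### Fidelity modes and numerical choices

* **full** — step `5e-5` s, signals saved over 1940–2000 s at 0.01 s
  sampling, second stationarity window 2940–3000 s. One run takes about a
  minute of CPU. At baseline the two-window drift of every index is below
  0.01%.
* **fast** — step `1e-3` s, 120 s span with the last 60 s saved. This is the
  mode used throughout the test suite; it agrees with full mode within about
  3% (flow-derived indexes are worst; most agree well within 1%).
* The cardiac phase `u` integrates `du/dt = 1/T` and is wrapped to `[0, 1)`
  after each step; a sample where `u` decreases marks the start of systole.
* A non-finite state aborts the run and is reported as a structured failure
  object carrying the offending time, so a population run records the
  subject as rejected (`integration_failure`) and continues.
* Window averages of flow-derived indexes carry ~1% of respiratory
  modulation noise whenever the window covers a non-integer number of
  respiratory periods; the full-mode window offset (1000 s = 250 respiratory
  periods) cancels this exactly, which is why the stationarity criterion is
  evaluated there.

## Index extraction

`detect_cycles()` finds complete cardiac cycles from phase resets;
incomplete boundary cycles are discarded, never extrapolated. Per cycle:
CDBP/MAP/CSBP are the min/mean/max of the arterial pressure waveform, CPP
their difference; CVP, CO, SaO2, PaO2, PaCO2 are means of the thoracic-vein
pressure, aortic-valve flow and arterial gas signals; SV is per-cycle CO
times the heart period; EF comes from the extremes of left-ventricular
volume. Per-cycle values are then averaged arithmetically over the save
window (robust to unequal cycle lengths), and HR is 60 over the mean heart
period — the alternative `mean(60/T)` convention differs only at second
order in the period variability. Extrema are taken over sampled points
without sub-sample interpolation, so the 0.01 s sampling period bounds the
extremum error.

## Virtual populations

Two presets mirror the two study populations: `vp1` (9 sampled dimensions;
total blood volume, venous unstressed volume, the basal cardiac cycle linked
co-monotonically with the vagal gain, baroreflex activation level, basal
maximum LV elastance, FiO2, hemoglobin, CO2 saturation and the CO2
dissociation exponent) and `vp2` (10 dimensions; the three ventricular
elastance parameters move together, and the dissociation-curve constants are
individually varied). Linkage expands one Sobol' coordinate affinely into
every member parameter, so a linked parameter sits at its lower bound
exactly when its partners do.

Sampling uses scrambled Sobol' sequences (Joe–Kuo direction numbers; a
random lower-triangular linear matrix scramble plus digital shift drawn from
the seed). Scrambling preserves the digital-net structure — at power-of-two
sizes every dyadic cell of the matching volume holds the same number of
points — while making the point set seed-randomized; the test suite verifies
marginal uniformity (Kolmogorov–Smirnov), stratification, and
reproducibility.

Filtering applies the two exclusion criteria: (1) stationarity — any index
drifting by more than 1% between the two save windows (with an absolute
fallback tolerance of 0.1 unit when the first-window mean is below 0.5 unit,
since the percentage rule is undefined near zero — CVP can approach 0); and
(2) admissible range — any index strictly outside its physiological or
pathological bounds (bounds inclusive, since the rule excludes subjects that
*fall outside* the range). Every violated criterion is recorded, not just
the first. Classification then labels accepted subjects by strict cutoffs
(bradycardia HR < 60; hypertension CSBP > 130 or CDBP > 80 or MAP > 100 —
one label by design, since all three rows name the same condition; reduced
cardiac function EF < 50; hyper-/hypo-ventilation PaCO2 < 35 / > 45);
multiple labels may coexist and an empty label set means healthy.

`convergence_errors()` reports `|e_n - e_ref| / |e_ref| * 100` for each
summary statistic against the largest-n reference, and
`split_population()` performs the seeded 80/20 shuffle split
(1789 accepted subjects split into exactly 1431 + 358).

## The analytic surrogate

`surrogate_simulate()` is a fast stand-in for the ODE model used to test
every pipeline stage in milliseconds. Each primary index responds as
`mid + half * tanh(gain * x)` where `x` is a signed, L1-normalized
combination of the normalized parameters whose signs follow the reference
local-sensitivity ranking, `mid`/`half` anchor the response inside the
admissible range widened by 20% per side (so the range filters genuinely
trigger), and the default gain 0.9 concentrates responses so that roughly
three quarters of sampled subjects pass the filter — enough rejected
subjects to exercise the bookkeeping, enough accepted ones to train on.
Derived indexes are built for exact internal consistency: CPP = CSBP −
CDBP, MAP = CDBP + CPP/3, SV = CO·60/HR, and ventricular volumes consistent
with EF. A latent confounder — a smooth but high-frequency function of
parameters absent from the CVP sensitivity table — feeds only the CVP
driver, so CVP is partially unpredictable from the wearable features; this
reproduces the qualitative failure mode of CVP prediction on a shifted
population while leaving tabled-pair monotonicity exact.

What passing surrogate tests do **not** show: the surrogate has no waveform
dynamics, no genuine parameter interactions beyond the saturating
nonlinearity, and synthetic magnitudes; it demonstrates that the pipeline's
statistics are computed correctly, not that the physiology is right — that
is the reference simulator's job.

## Gaussian-process regression

One exact GP per target, kernel
`sigma_f^2 * exp(-||x−x'||²/(2 l²)) + sigma_n² I` (a constant-variance times
squared-exponential product plus noise), fitted by Cholesky decomposition on
z-scored features (statistics from training data only). The prior mean is
the training-target mean; targets keep their physical units, and
cross-validation scores are computed in those units because the reported
errors are physical. Hyperparameters are chosen by randomized search — 50
draws of (signal SD, length-scale, noise SD) from log-uniform ranges
`[1e-1, 1e2]`, `[1e-1, 1e2]`, `[1e-8, 1e-1]` — scored by 10-fold shuffled
cross-validation minimizing the maximum absolute error, then refitted on the
full training set. A fixed `1e-8` diagonal jitter guards the factorization
when the sampled noise is tiny. All seeds (draws, folds, splits) are stored
in the model object, and identical data plus identical seeds reproduce
identical hyperparameters.

`learning_curve_gpr()` holds the CV folds fixed across training sizes and
subsamples only the training portion, so scores at different sizes are
evaluated on identical validation sets; on the fixture population the
maximum error at 300 training samples is at or below its value at 100,
matching the finding that about 300 subjects suffice.

## Error propagation

Wearable acquisition errors are modelled as independent uniform boxes around
each test point: ±5% of HR, ±3 mmHg on both pressures (wearable error plus
peripheral-to-central transfer-function bias, combined), ±2% of SaO2. Each
box is sampled with `N` scrambled-Sobol' points from a stream derived from
(seed, point index) — results are independent of evaluation order — the
model is evaluated on each sample, and per point the expected prediction E
and SD are estimated. REPI = 100·|E − y|/|y| by default without a
denominator guard, matching the headline definition literally (a
configurable guard exists); CV = 100·σ/E uses the estimated E. The module's
oracle is the affine closed form: a uniform box pushed through an affine map
has mean at the box midpoint and SD `sqrt(sum(coef² eps²)/3)`, which the QMC
estimate reproduces within 1% at N = 1000. Convergence in N is reported for
N ∈ {50, 100, 500, 1000}.

## Sensitivity analysis

The local score is the dimensionless logarithmic sensitivity
`S = (P/M) dM/dP` with a centered finite difference at a 10% relative step:
exact on quadratics, O(h²) otherwise, invariant to rescaling of output or
parameter units. Rankings break ties lexicographically for reproducibility,
and per-entry failures (zero baseline output, model failure at a perturbed
point) are recorded rather than raised.

Total-order variance-based indices have two routes. Given a model function,
a Sobol' pick-and-freeze scheme with the Jansen estimator
(`mean((f(A) − f(AB_i))²) / (2 Var f)`) is the reference; it is
cross-checked in the tests against a brute-force double-loop variance
decomposition on 2-D models. Given only an already simulated population, a
given-data estimator fits an orthonormal polynomial HDMR expansion (shifted
Legendre main effects to degree 3 plus bilinear pairwise interactions) by
least squares and reads the indices off the coefficient variances; its exact
truncation is a documented choice, with the function-route estimator as the
correctness surface. Indices are normalized per output to sum to one;
sub-threshold values are suppressed only in display, never in the data.

## Problem sizes

The test suite and the acceptance script run on one CPU with: fixture
populations of 1024 subjects (about 800 accepted, training sets of 650),
full tuning budgets of 50 randomized-search iterations, propagation with
N = 256 boxes per test point for study metrics and N = 1000 for the affine
oracle, and 4096-point Sobol' sets for the estimator oracles. The
full-fidelity simulator run (about one minute per subject) is exercised once
in development and documented here; the suite uses fast mode.

## Known limitations

* The reference simulator is a reduced model: no sympathetic control of
  contractility or vascular tone, fixed metabolic rates, no transport
  delays, single venous pool. Population-level acceptance rates and
  sensitivity magnitudes therefore differ from richer models; only the
  baseline envelope, the signs of the leading sensitivities, and the
  pipeline contracts are treated as load-bearing.
* Strict per-step monotone convergence of every summary statistic with
  sample size is not guaranteed for filtered populations (the accepted
  subset changes with n) nor for CVP (the confounder is not QMC-nested);
  the tests assert the robust form (largest n at least as accurate as the
  smallest, medians monotone).
* Measurement errors are independent uniform boxes — an average-case
  approximation; individual-specific or temporally correlated sensor error
  models are out of scope.
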