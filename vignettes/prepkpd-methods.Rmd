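---
title: "Methods: linked plasma-intracellular-dNTP PKPD of TDF/FTC"
author: "prepkpd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linked plasma-intracellular-dNTP PKPD of TDF/FTC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepkpd)
```

## The model

`prepkpd` implements a population pharmacokinetic-pharmacodynamic model of
oral tenofovir disoproxil fumarate / emtricitabine (TDF/FTC), the
co-formulated backbone of HIV treatment and pre-exposure prophylaxis
(PrEP). One *chain* couples three linked subsystems for one analyte:

1. **Plasma** — a classical two-compartment disposition model with
   first-order absorption (depot `A1`, central `A2`, peripheral `A3`),
   parameterized by `Ka`, `Vc/F`, `CL/F`, `Vp/F`, `Q/F`. The observable is
   the plasma concentration `C = A2/(Vc/F)` in ng/mL.
2. **Intracellular anabolite** — the active phosphorylated form (TFV-DP or
   FTC-TP) in peripheral blood mononuclear cells, in fmol per million
   cells. Because plasma (ng/mL) and cellular (fmol/10^6 cells) amounts
   carry incommensurable units, no mass is transferred: plasma
   concentration *drives* anabolite formation. The link is a hybrid of
   first-order formation and saturation,
   \deqn{\frac{dA_4}{dt} = \frac{K_f\,C}{1 + A_5/SC_{50}} - K_{el}A_4 +
     A_6 K_{el} R, \qquad
     \frac{dA_5}{dt} = K_f\,C - \frac{CL}{V_c}A_5, \qquad
     \frac{dA_6}{dt} = (A_4 - A_6)K_{el}R,}
   where `A5` is a virtual *saturation* compartment (its level, built up by
   recent plasma exposure and eliminated at the plasma rate `CL/Vc`,
   attenuates formation with half-inhibition at `SC50`), and `A6` is a
   *recycling* compartment exchanging with the anabolite pool at rate
   `R * Kel`. The recycling fraction `R` in [0, 1) splits elimination into
   a fast central route `(1 - R) Kel` and a slow re-entry route, producing
   the biphasic anabolite washout seen in the data. Both `A5` and `A6` are
   mathematical constructs, not physiological spaces.
3. **dNTP pool** — each endogenous deoxynucleoside triphosphate that the
   analog competes with (dATP and dGTP for tenofovir, dCTP and TTP for
   emtricitabine) follows an indirect-response Emax model in which the
   anabolite inhibits the zero-order production rate:
   \deqn{\frac{dA_7}{dt} = K^0_{in}\Bigl(1 - w(t)\,
     \frac{E_{max} A_4}{A_4 + EC_{50}}\Bigr) - K_{out}A_7,}
   with `Emax` and `Kout` fixed to 1 and `K0in = R0 * Kout` so the
   drug-free steady state is the baseline `R0`. For dGTP the inhibition
   wanes with time on drug through `w(t) = 1/(1 + t^gamma)` (`t` = days
   since the first dose, so `w(0) = 1`); all other pools have `w = 1`.
   The waning factor multiplies the whole inhibition term — the minimal
   reading of a "simplified by `1/(1 + time^gamma)`" effect — and its
   clock starts at each subject's first dose (for simultaneous starts the
   two possible conventions coincide).

Shipped typical values, covariate coefficients and variability for both
chains are available as `tfv_chain_params()` / `ftc_chain_params()` and as
YAML fixtures (`load_params("tfv_chain.default")`). Two covariates act
linearly on typical values: males have a larger FTC central volume
(`Vc/F = 99.4 + 24.3 * sex` L, +24.4%) and HIV-positive subjects a faster
FTC-TP formation rate (`Kf = 41.6 + 31.3 * hiv` /day, +75.2%).

### Units

Time is in days throughout (all rate constants are per day). Doses are
entered in micrograms of *parent-drug equivalents*: one TDF 300 mg tablet
delivers 136 mg tenofovir (136,000 ug), one FTC tablet 200 mg
(200,000 ug). With volumes in liters, `A2/(Vc/F)` is ug/L = ng/mL, the
plasma assay unit; this is the only convention that reconciles the shipped
clearances (e.g. TFV `CL/F` = 1410 L/day) with typical plasma exposures of
a few hundred ng/mL. `SC50` carries plasma concentration units because the
saturation compartment is driven by `Kf * C` and eliminated at `CL/Vc`;
the unit conversion from ng/mL driving to fmol/10^6 cells response is
folded into `Kf`, consistent with the no-mass-transfer design.

## Simulation

The plasma and saturation blocks are linear, so under bolus dosing both
have exact sum-of-exponentials solutions. The default integration route
(`simulate_chain(..., method = "analytic")`) evaluates these closed forms
and numerically integrates only the nonlinear states (anabolite, recycle,
dNTPs) with `deSolve::lsoda` at `rtol = 1e-8`, `atol = 1e-10`; this avoids
dose-event restarts entirely and is fast enough for Monte-Carlo work. A
full event-driven 8-state integration (`method = "ode"`, doses added to
the depot as bolus events with a solver restart at each event) is retained
as an independent route; the test suite checks the two agree to better
than 1e-5 relative. No dose lag time is modeled.

Trajectories start with all drug compartments at zero and each dNTP pool
at its baseline, so an empty regimen yields identically zero drug and a
flat baseline — a structural fixed point the tests assert exactly.

## Population model

Between-subject variability is lognormal and independent across
parameters: `param_i = tv * exp(eta)`, `eta ~ N(0, omega^2)` (no
covariance matrix is estimated or shipped; inter-occasion variability is
not modeled). The shipped `omega^2` values follow the convention
`%CV = 100 * sqrt(omega^2)` (e.g. 0.288 -> 53.7%CV), which the tests
verify against the printed pairs; the alternative
`CV = sqrt(exp(omega^2) - 1)` convention differs only in the third digit
at these magnitudes. Residual error is exponential
(`y = pred * exp(eps)`) for plasma and dNTP streams and proportional
(`y = pred * (1 + eps)`) for the intracellular analytes; proportional
draws below zero are clipped to zero and flagged, and fall below the
quantification limit downstream. One exponential-stream residual variance
(dGTP, 0.267) is reconstructed from its printed %CV via the same
convention because no direct estimate is available.

The individual dNTP baseline — known only from a single pre-dose sample —
uses a shrinkage estimator (`baseline_r0()`) that weights the population
mean and the observed value by `sigma^2/(omega^2 + sigma^2)` and
`omega^2/(omega^2 + sigma^2)` respectively, with the residual random
effect entering through an exponent scaled by the same weight. The
estimator is implemented verbatim, including that unusual residual-scaled
exponent; its limits (population value when `omega^2 = 0`, observed value
when `sigma^2 = 0`) and its interpolation property are asserted in the
tests.

Virtual populations default to HIV-negative subjects with sex drawn
Bernoulli(0.675), the study's demographic (27 of 40 male); both are
configurable.

## The synthetic trial generator

`generate_trial()` emulates the intensive study design the model was
built for: 21 HIV-negative subjects dosed daily for 30 days (full
profiles at 1, 2, 4, 8, 24 h post-dose on days 1 and 30; pre-dose, 2 and
8 h on days 3, 7 and 20; single washout samples on days 35, 45 and 60)
and 19 HIV-positive subjects dosed for 60 days with a single day-60
sample. dNTPs are sampled at baseline, across day 1, and at 8 h post-dose
at later visits. Pre-dose samples are taken at trough, 24 h after the
previous dose — the clock times of "pre-dose" draws are not otherwise
pinned down.

Censoring reproduces the assays: plasma LLOQ 10 ng/mL; per-sample limits
of 2.5 fmol (TFV-DP), 0.1 pmol (FTC-TP) and 50 fmol (dNTPs) are converted
to per-10^6-cells thresholds through a lognormal cells-per-sample draw
(median 5e6 cells, CV 50% — a realistic PBMC yield; the assays specify
per-sample limits only). Observations below the limit are flagged BLQ and
carry no value ("treated as missing"); with the shipped parameters BLQ
flags concentrate in the washout phase, as in the study. The HIV-positive
arm is simulated without any efavirenz effect (the model carries no EFV
parameter), and dropout is not simulated.

What the generator deliberately does *not* emulate: correlated random
effects, inter-occasion variability, assay batch effects, dropout, and
any intracellular TFV/FTC interaction (the drugs were always
co-administered, so the data could not inform one). Tests that pass on
generated data therefore validate the implementation against its own
model class, not the model against biology.

`predictive_check()` simulates replicate trials under a dataset's design
and reports, per observation, the 5-95% prediction interval across
replicates; the fraction of quantifiable observations outside the 90%
interval is calibrated near 10% under the data-generating model, and the
conventional acceptance rule is < 15%.

## Estimation

The original analysis used FOCEI in NONMEM with sequential linking
(upstream individual parameters fixed before fitting each downstream
model). This package deliberately does **not** reimplement marginal
mixed-effects likelihoods. `fit_stage()` minimizes residuals on the
error-model scale (log residuals for exponential streams, relative
residuals for proportional ones), with BLQ rows excluded,
Levenberg-Marquardt optimization on transformed parameters (log scale;
logit for the recycling fraction `R`, whose near-collinearity with the
exchange rates motivated that parameterization), and seeded multi-start
jitter against local minima. Three pooling schemes are offered:

- `"pooled"` — one naive NLS over all observations. Exact in the
  noise-free limit (the consistency checks use it), but under strong
  lognormal between-subject variability the pooled curve is not the
  typical-parameter curve, so distribution parameters come back badly
  biased on noisy multi-subject data.
- `"two_stage"` — independent per-subject fits averaged on the
  transformed scale (geometric means). Classical, but fragile when a
  parameter is weakly identified per subject (`Ka` runs away).
- `"map"` — iterative two-stage MAP, the recommended estimator:
  per-subject empirical-Bayes etas for the parameters carrying
  `omega^2`, penalized by `eta^2/omega^2`, alternate with pooled updates
  of the typical values; parameters without variability stay common to
  all subjects. With the shipped variances this recovers `CL/F` and
  `Vp/F` to within a few percent on study-sized synthetic trials, but it
  retains the known shrinkage bias of MAP-based estimation on the
  distribution parameters (`Vc/F` high, `Q/F` low by on the order of
  10-20%): a joint penalized-MAP fit over all subjects lands on the same
  values, so the bias belongs to the objective, not the optimizer, and
  removing it would require exactly the marginal-likelihood machinery
  this package declines to reimplement. The tests state this honestly
  rather than hiding the parameters it affects.

`map_plasma_individuals()` exposes the per-subject empirical-Bayes step
(penalized by `eta^2/omega^2`) used for sequential linking. The reported
objective is the surrogate `n log(RSS/n)`, not a NONMEM OFV, so
objective-function values are not comparable across estimators;
`lrt_covariate()` applies the staged covariate thresholds (forward
inclusion at a 6.64-point drop, backward retention at a 10.8-point rise)
as pure threshold arithmetic.

Two numerical details matter. First, the anabolite forcing for the dNTP
stage is precomputed on a dose-aware grid (nodes clustered just after
each dose where the trajectory kinks) and interpolated, since it does not
depend on the fitted parameters. Second, the finite-difference step of
the optimizer is set well above the ODE integration noise (`epsfcn`);
without this, weakly identified directions — notably `EC50` when exposure
sits far below it — lose their gradient in solver noise and the fit
stalls on a plateau. `Ka` is intrinsically weakly identified by designs
whose first sample falls at 1 h post-dose (absorption is nearly complete
by then), so recovery checks target the disposition parameters.
A dNTP fit against data with no anabolite exposure returns a flagged
non-convergence, never a number.

## Derived metrics

Phase half-lives come from closed-form eigenvalues: the plasma
disposition matrix (`k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`) and the
intracellular pair (`k40 = (1-R) Kel`, `k46 = k64 = R Kel`). At the
shipped values these give plasma terminal half-lives of 16.9 h (TFV) and
26.2 h (FTC) and TFV-DP phases of 72.7 h / 55.7 d. For FTC-TP the
eigenvalue phases (10.1 h / 79.6 h) deviate from the reported 8.8 h /
76.8 h by more than input rounding explains; the regression windows
behind those published slopes are unknown, and no window tuning is
attempted — the eigenvalue results are reported as-is with this
discrepancy documented.

Because the plasma-to-cell link is nonlinear, conventional half-lives do
not predict accumulation; the *operational multiple-dosing half-life* is
the dosing interval `tau` at which a steady-state ratio equals 2, located
by simulating 50 doses of the typical subject per candidate `tau` and
bisecting to `|ratio - 2| < 1e-4` so the answer is independent of any
coarse grid. Two criteria are provided: `Cmax,ss : Cmax,fd = 2` (peak
doubling from first dose to steady state) and `Cmax,ss : Cmin,ss = 2`
(50% peak-to-trough elimination at steady state). For a linear
one-compartment system both criteria cross at the elimination half-life —
a property the tests verify by brute force on a fast-absorption test
chain — while the saturation nonlinearity pushes the two crossings apart
for the real chains. Default search ranges are 1-9 days (TFV-DP) and
0.05-2.5 days (FTC-TP); the FTC lower bound sits below the conventional
0.2-day grid edge so that a crossing near that edge is properly
bracketed. At the shipped parameters the searches give TFV-DP 6.74 d
(peak:trough) and 4.19 d (peak:first-dose), and FTC-TP 31.6 h
(peak:trough). The FTC-TP peak:first-dose crossing lands near 14 h,
far from the 4.8 h (= 0.2 d, exactly a conventional grid edge) sometimes
quoted; a crossing at 0.2 d would require the steady-state peak to be
only twice the first-dose peak at five doses per day, which is
inconsistent with `Kel = 1.6`/day plus formation sustained by plasma FTC
(terminal half-life 26.8 h) — the same constants that do reproduce the
33 h peak:trough value. The discrepancy is reported, not tuned away.

`dntp_reduction_profile()` reports the fractional pool reduction
`1 - A7/R0` under repeated dosing; the summary timepoint is the
steady-state trough (24 h after the last dose, matching the
trough-oriented sampling emphasis), where the typical subject shows ~8%
dATP and ~11% dCTP reductions — the within-interval readout time moves
these by a few points, which is why they are asserted as brackets rather
than point values. The dGTP effect wanes: its reduction reaches an
interior nadir within the first days of dosing and then relaxes back
toward baseline.

## On-demand PrEP simulation

`simulate_prep()` runs the event-driven regimen: a double dose 2-24 h
before a coitus event at `t = 0` (the two pre-coitus tablets are taken
together as one double-dose event — the natural reading of "two doses"
taken at one sitting), then single doses at +24 h and +48 h, simulated
over 7 days in a virtual HIV-negative population. The efficacy surrogate
is the molar ratio of analog to its competing substrate (TFV-DP:dATP,
FTC-TP:dCTP, both fmol/10^6 cells), with the denominator the subject's
own simulated pool including its drug-induced reduction — drug kinetics
dominate the ratio, but the reduction is carried through rather than
frozen at baseline. Exceedance is summarized against in-vitro viral
suppression thresholds (TFV-DP:dATP EC50 0.086; FTC-TP:dCTP EC50 0.022,
EC90 0.07) at the moment of coitus itself (`t = 0`), and percentile bands
(5th-95th by 5) over time. At `n = 1000` the Monte-Carlo error of an
exceedance percentage is a few points.

## Problem sizes and numerical choices

Simulation-heavy checks are sized to run on a laptop core: predictive
checks use 100+ replicates of reduced cohorts, recovery experiments use
the study-sized 21+19 trial for the (closed-form) plasma stage and
single-subject noise-free fits for the ODE-driven stages, and the
operational-half-life searches evaluate a few dozen 50-dose simulations
each. Solver tolerances are fixed (`1e-8`/`1e-10`; tighter for the
one-state dNTP stage predictions) so deterministic outputs are
reproducible to more digits than any comparison uses. Every stochastic
entry point takes an explicit seed and restores the caller's RNG state.

## Known limitations

- Typical-value estimation is pooled NLS, not FOCEI: variance components
  (`omega^2`, `sigma^2`) are taken as known inputs, not estimated, and
  objective values are not NONMEM-comparable.
- The recycling compartment is a descriptive construct; its slow phase
  (55.7 d for TFV-DP) rests on sparse washout sampling in the design the
  model emulates and should not be over-interpreted.
- PBMC concentrations stand in for target-tissue cells; no
  tissue-compartment extrapolation is attempted, and no TFV-DP:dATP EC90
  threshold is shipped (no reliable value to transcribe).
- Simultaneous (joint) estimation across links is out of scope, as is
  bootstrap-based model evaluation.
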