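---
title: "Methods: concentration-dependent chloroquine toxicity modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: concentration-dependent chloroquine toxicity modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `cqrisk`, the
assumptions behind them, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate.

## 1. The concentration-fatality model

Self-poisoning outcomes are modelled as Bernoulli draws whose logit-scale
probability is linear in the log peak whole-blood *parent-drug*
concentration:

* Patients whose blood was sampled repeatedly and whose concentration
  peaked **after** admission contribute their observed peak `x`:
  `logit p = alpha + beta * log(gamma * x) + a_cohort`.
* All other patients contribute their admission value with a shared
  log-scale shift `delta` standing in for the unobserved peak:
  `logit p = alpha + beta * (log(gamma * x) + delta) + a_cohort`.

Assumptions worth making explicit:

* `delta` is a single shared average shift, not a per-patient latent
  variable. A per-patient latent-peak model would be more flexible but is
  intentionally out of scope; the shift is identified mainly by its
  informative Exponential(rate 8) prior, whose rate is exactly the
  maximum-likelihood exponential rate computed by `delta_prior_rate()`
  from patients with observed in-hospital peaks (rate = 1 / mean log gap).
* Conditional on peak concentration, mortality is assumed equal for
  patients peaking before and after admission. In reality those peaking in
  hospital were supported earlier relative to their peak; the direction of
  that bias is known but its size is not measurable from these data.
* The metabolite correction `gamma` multiplies the measured concentration
  because the spectrophotometric assay co-measures desethylchloroquine.
  `gamma` and `delta` are not jointly identifiable from outcome data
  alone, hence both carry informative priors (Normal(0.7, 0.065),
  truncated to (0,1), and Exp(8)).
* Cohort intercepts `a_cohort ~ Normal(0, 0.5)` absorb differences in
  intensive-care support across the three hospital series. All
  population-level outputs (threshold inversion, fatality curve, risk
  projection) fix the cohort offset at 0: the offsets encode historical
  standard-of-care differences and the reported single curve implies a
  reference level. This is configurable by operating on the draws
  directly.

Priors (all overridable via `mortality_priors()`): `alpha ~ N(-15, 1)`
— about a 3e-7 death probability at 1 µmol/L; `beta ~ N(4, 1)`;
`gamma ~ N(0.7, 0.065)`; `delta ~ Exp(8)`; cohort offsets `N(0, 0.5)`.

**Threshold inversion.** Per posterior draw,
`c(p) = exp((logit(p) - alpha) / beta)` is the parent-drug peak
concentration with predicted mortality `p`. Draws with `beta <= 0`
(possible under the Normal prior, never observed in practice) cannot be
inverted and are excluded with a logged count. Whether the headline
threshold should be the posterior mean or median of the draw-wise
thresholds is not obvious; `concentration_at_mortality()` reports both
(they differ by ~3% here).

## 2. The QRS Emax model

QRS duration rises sigmoidally with whole-blood concentration from the
drug-free mean `e_min` to an upper asymptote `e_max`, with midpoint `e50`
on the log10 scale and slope `k` (sampled as `log k`). Three design points
deserve comment:

* **Drug-free rows.** Zero concentrations cannot enter the sigmoid
  (log10 undefined). The 32 drug-free volunteer measurements instead
  contribute `QRS ~ Normal(e_min + b_subject, eps3)`: they pin down the
  lower asymptote and the subject intercepts. This matches the sigmoid's
  own zero-concentration limit, so the likelihood is continuous in spirit.
* **Error strata.** Measurement error is stratum-specific: manually read
  ECGs from the largest self-poisoning series (stratum 1, prior
  `eps1 ~ N(25, 5)` msec), the later cohort (stratum 2, `N(15, 5)`), and
  automated volunteer readings (stratum 3, `N(2, 1)`). Concentration-
  dependent heteroskedasticity beyond these strata is deliberately not
  modelled. Stratum-1 observations additionally carry an additive reading
  bias (`N(-20, 5)` msec), implemented as an offset on the model mean; an
  equivalent view is that it corrects the data upward. A test verifies
  the exact reparameterisation: shifting stratum-1 data and the bias
  prior together leaves every other posterior unchanged.
* **Concentration harmonisation.** Volunteer plasma is multiplied by 4
  (whole blood : plasma partition); self-poisoning admission values by
  0.7 (removing the metabolite from the assay signal). Rows from the
  first cohort carrying QRS values — none exist in the clinical series —
  would be assigned stratum 2 (no reading bias).

Identifiability: `(e_max, e50, k)` sit on a ridge because few
observations approach the upper asymptote. The *curve* over the observed
concentration range is well identified (and is what the tests check);
the individual parameters are constrained mainly by their priors. This is
expected behaviour for sigmoid Emax models fitted to one-sided designs.

## 3. Population PK simulation

Both disposition models are linear: a chain of transit compartments
(`ktr = (n_transit + 1) / MTT`, last transit emptying into the central
compartment at `ktr`) feeding a two-compartment (whole blood) or
three-compartment (plasma) mammillary system.

Numerical choices:

* Profiles are propagated **exactly** with one matrix exponential of
  `A * dt` per individual (RcppArmadillo `expmat`), with oral doses as
  boluses into the first transit compartment. No ODE solver error enters;
  a test shows agreement with an independent `deSolve::lsoda` integration
  at 1e-6 relative tolerance, and superposition/dose-linearity hold to
  machine precision.
* Grid resolution is 0.25 h from first dose to 7 h after the last dose.
  Absorption peaks 1–6 h after a dose, so a 15-minute grid bounds the
  C_max discretisation error well below reporting precision (halving the
  step moves C_max by < 0.5%, asserted in tests).
* mg base → µmol uses a chloroquine base molar mass of 319.87 g/mol, held
  as a package constant.
* Allometric scaling uses exponent 0.75 on clearances and 1 on volumes,
  from a reference weight of 70 kg (overridable in the parameter file).
* Between-subject variability is log-normal per parameter; no
  inter-occasion variability is simulated.
* Tablet rounding for weight-based regimens: nearest whole 155 mg tablet,
  exact half-tablet ties rounded **up**, minimum one tablet. Tie-breaking
  is an assumption; no half-tablets are allowed. The malaria regimen's
  daily doses are taken 24 h apart.

**The parameter file is synthetic.** The published fixed effects and
omegas for the two disposition models are not printed in the source
literature available to this package, so
`inst/extdata/pk_parameters_synthetic.yaml` contains a stand-in set with
the correct structural form, calibrated once so the typical 70-kg
whole-blood simulation reproduces reported exposure summaries: median
C_max ≈ 10.7 µmol/L under 600 mg bid × 10 d with ≈ 60% of individuals
above 10 µmol/L; ≈ 2/1000 above 10 µmol/L under the 10-day 310 mg bid
regimen; a > 3× lower malaria-regimen median; and a plasma model agreeing
in the median under the ×4 ratio while spreading less. Anyone holding the
published NONMEM estimates can drop them into the same YAML schema and
pass the file path to `pk_model_parameters()`.

## 4. Risk projection

For each posterior draw `j` and simulated individual `i`,
`p_ij = logit^-1(alpha_j + beta_j * log(cmax_i))`, set to zero when below
the 1% floor (the floor concentration varies with the draw — truncation
is applied per (individual, draw) pair). Draw-wise means over individuals
give the fatality distribution; its mean and central 95% interval are
reported per 1000. Exceedance is reported both against the draw-wise 1%
threshold (posterior mean fraction) and against the fixed 10 µmol/L
"danger zone" cutoff. Uncertainty is propagated by nesting: all PK
individuals are evaluated under all posterior draws (a `n_draws` cap
exists for very large posteriors). Averaging over draws after truncation,
rather than truncating the draw-averaged curve, follows from applying the
floor within each draw.

## 5. The synthetic-data generator

`simulate_poisoning_cohort()` draws measured peak concentrations
log-normally (defaults `meanlog 2.925`, `sdlog 0.85`, calibrated by
quadrature so that ~11% of patients die under the default logistic truth
— these two numbers are calibration products, not estimates), admission
values as `peak * exp(-gap)` with per-patient exponential gaps (mean
0.125, matching the Exp(8) prior), cohort labels in proportions
11 : 247 : 44, deaths from the logistic model and QRS values from the
Emax mean (at the parent-drug peak) with stratum noise and the cohort-2
reading bias. `simulate_volunteer_study()` gives each subject two
drug-free QRS rows and twelve rows pairing QRS with plasma concentrations
simulated from the plasma PK model after a single 620 mg dose.

What the generator does *not* emulate: vomiting and time-to-hospital
dynamics, co-ingested drugs, treatment covariates (ECMO, vasopressors)
beyond the cohort intercepts, concentration-dependent QRS
heteroskedasticity beyond the three strata, and any misspecification of
the parametric forms. Passing parameter-recovery tests therefore shows
the inference machinery is correct *under the assumed model*; it cannot
show the model is right for real patients.

## 6. Test and pipeline problem sizes

Parameter recovery uses cohorts of 3000 patients (fatality model) and
16 volunteers + 300–400 patients (QRS model) with 2–4 chains of
2000–4000 iterations, half discarded as burn-in, which yields R-hat near
1 and effective sizes in the hundreds for the slowest-mixing parameters.
The full-length configuration used for final inference
(8 chains × 1e5 iterations, thinning every 100, 4000 retained draws) is
available through the same arguments. A dense-grid posterior on a
bounded 4-dimensional box (41 × 41 × 113 × 51 nodes spanning > 4 prior
SDs per parameter) serves as the sampler-independent oracle for a
10-record cohort. PK populations use 1000 individuals per
regimen × weight cell; weights run 40–90 kg in 5 kg bands.

## 7. Known limitations

* The δ-shift model ignores between-patient variation in the
  peak–admission gap when the peak is unobserved.
* Compartmental models only approximate chloroquine's distribution-
  dominated kinetics; terminal elimination (half-life > 1 month) is not
  meaningfully estimable and the two-compartment model underestimates it,
  which matters little over the first treatment weeks.
* The PK parameter set is a calibrated stand-in: absolute risk
  projections inherit its calibration targets, and upper-tail C_max
  behaviour is unverifiable without large population PK studies.
* No hydroxychloroquine-specific predictions: its toxicity thresholds are
  not identifiable from chloroquine self-poisoning data.
* QT/JT modelling is out of scope; QRS widening is the toxicity marker.
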