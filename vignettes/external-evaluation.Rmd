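---
title: "External evaluation of population PK models with pkeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{External evaluation of population PK models with pkeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pkeval implements the evaluation battery used to judge whether a published
population pharmacokinetic (PK) model transfers to a new population:
prediction-based bias and precision statistics, goodness-of-fit residuals,
prediction-corrected visual predictive checks (pcVPC), and normalized
prediction distribution errors (NPDE). The motivating setting is sparse,
opportunistically sampled pediatric data for a parent drug and its active
metabolite (risperidone / 9-OH-risperidone), where models must be compared
without re-estimating any of their parameters.

This vignette documents the models, the statistical procedures, the choices
that were genuinely open, and what the shipped tests do and do not
demonstrate.

## The model family

A `pk_model` describes a joint parent--metabolite compartmental model with:

* **Structure.** One or two disposition compartments for the parent, an
  optional one-compartment metabolite formed from the parent, first-order
  absorption from an oral depot with an optional lag time. All clinically
  used enteral routes (oral, NG/OG, nasojejunal, transpyloric, G-tube,
  J-tube) are mapped to this single absorption pathway, since no evaluated
  model structure distinguishes routes.
* **Typical values (theta).** Clearances in L/h, volumes in L, `ka` in 1/h,
  `ALAG` in h, the fraction metabolized `fm` in (0, 1], bioavailability `F`.
  Internally all amounts are nmol and all concentrations nmol/mL;
  conversion from ng/mL and mg uses the analyte molecular weights
  (410.485 g/mol for risperidone, 425.91 g/mol for 9-OH-risperidone), so a
  0.100 ng/mL quantitation limit is 2.4361e-4 nmol/mL.
* **Inter-individual variability.** Log-normal random effects with
  covariance `omega`: parameters are multiplied by `exp(eta)`.
* **Mixture subpopulations.** A finite mixture (e.g. poor / intermediate /
  normal metabolizers) with fixed mixing proportions; each class overrides
  selected typical values, usually the parent clearance and `fm`.
* **Covariates.** Power or linear terms; the allometric preset scales
  clearances by `(wt/70)^0.75` and volumes by `(wt/70)^1`.
* **Residual error.** Per analyte, additive (nmol/mL) plus proportional
  components on the natural scale, or an additive log-scale error for
  models fitted to log concentrations.

Individual parameters are resolved in a fixed order: mixture overrides,
then covariate terms, then `exp(eta)`. A covariate at its reference value
therefore changes nothing, and `eta = 0` with reference covariates returns
theta exactly.

The five shipped configurations (`model_library()`) span the structural
families in routine use for this drug pair: a 2-compartment parent plus
metabolite with lag ("a"), pediatric and adult 1-compartment joint
three-class mixture models without and with allometry ("b", "c", "d"), and
a 2-compartment parent-only two-class mixture model with log-scale error
("e"). **Their numeric values are representative fixtures** chosen to give
realistic pediatric concentration ranges; they are deliberately not
asserted to be any study's published estimates, which live in supplementary
material outside this package. Users evaluating real models should fill
configuration files with the published values.

## Solving the kinetics

Every supported structure is a linear compartmental cascade, so the amount
in each compartment after a single oral dose is a finite sum of
exponentials: the rates are the absorption constant, the parent disposition
eigenvalues, and the metabolite elimination constant, and the coefficients
follow from partial fractions (the Bateman cascade and its two-compartment
generalisation). Multiple doses superpose; a lag time shifts each dose's
input, not the observation grid. The solver is vectorised over parameter
sets, which is what makes 1000-replicate simulation of a whole study cheap.

Numerical choices:

* Near-coincident rate constants (e.g. `ka` equal to `CL/V`) make the
  partial-fraction coefficients blow up; rates closer than a relative 1e-9
  are nudged apart by a relative 1e-7, introducing profile errors far below
  the 1e-6 relative tolerance the solver is held to.
* A general stiff ODE integrator (`deSolve::lsoda`, `engine = "ode"`) sits
  behind the same interface. It serves as an independent numerical
  cross-check in the test suite (agreement better than 1e-6 relative on
  0--48 h grids for all structures) and as a mass-balance oracle.

## Simulation engine

`simulate_ensemble()` repeats the study `nsim` times: fresh subpopulation
and `eta` draws per subject and replicate, the noise-free profile over the
subject's actual dosing history, then residual error per observation
record. Each replicate has its own RNG stream derived from the master seed,
so replicate `r` is bit-identical whatever the total replicate count — a
deliberate choice that keeps regression tests stable when `nsim` changes.
Negative concentrations drawn under a natural-scale additive error are kept
by default (truncation is available) because the diagnostics compare
observed and simulated values under the same error model. Simulated values
are never LLOQ-censored: the diagnostics are computed on quantifiable
observations only.

## Individual-level estimation

With all population parameters fixed, `ebe_estimate()` maximises
`log p(y | eta, class) + log p(eta)` per candidate class (quasi-Newton from
three deterministic starts: 0 and ±0.5 prior SD), and combines the class
maxima with the mixing proportions through Bayes' rule to obtain each
subject's class posterior — a Laplace-style approximation that omits the
curvature term. A subject with no observations keeps `eta = 0` and the
prior class probabilities. The exported `mixture_posterior()` is the exact
Bayes rule on supplied log-likelihoods, stabilised by log-sum-exp.

`population_prediction()` (PRED) depends only on the design. For mixture
models the default PRED is the proportion-weighted average of the
per-class `eta = 0` profiles — the marginal mean at `eta = 0` — with a
`most_probable` switch for the alternative convention; which convention a
given NONMEM run used is often ambiguous, so both are provided and neither
is asserted as canonical.

CWRES follow the first-order-conditional construction: finite-difference
linearisation of the individual prediction around the MAP `eta` (relative
step 1e-4, model-agnostic by design), marginal covariance
`G %*% omega %*% t(G)` plus the residual covariance at the individual
prediction, and Cholesky whitening of `y - f(eta_hat) + G eta_hat`. For
log-scale models the residuals are formed on the log scale.

## Prediction-based metrics

`prediction_metrics()` pools all observation records (no per-subject
averaging) and computes, with the `PRED - OBS` orientation,

$$\mathrm{PE} = \tfrac1N\sum(\mathrm{PRED}_i-\mathrm{OBS}_i),\quad
\mathrm{RMSE} = \sqrt{\tfrac1N\sum(\mathrm{PRED}_i-\mathrm{OBS}_i)^2},$$
$$\mathrm{MPE} = \tfrac{100}N\sum\frac{\mathrm{PRED}_i-\mathrm{OBS}_i}{\mathrm{OBS}_i},\quad
\mathrm{MAPE} = \tfrac{100}N\sum\left|\frac{\mathrm{PRED}_i-\mathrm{OBS}_i}{\mathrm{OBS}_i}\right|.$$

Under this orientation positive MPE means over-prediction. Published
reports sometimes describe positive MPE as under-estimation, which is
consistent with the opposite (`OBS - PRED`) orientation; this package
follows the formulas above literally and flags the ambiguity here rather
than guessing intent. PE and RMSE carry nmol/mL; division by OBS makes MPE
and MAPE scale-free but also heavy-tailed when observations sit near the
quantitation limit, which is why MPE values of hundreds of percent are
unremarkable for sparse pediatric data. The end-to-end report computes
these metrics on the natural concentration scale for every model (including
the log-scale model, so RMSE stays comparable in nmol/mL);
`log_scale = TRUE` is available for log-scale evaluation of PE/RMSE.

## Prediction-corrected VPC

`vpc_bands()` bins observations on time after first dose (default 8
quantile bins; ties on a bin edge go to the lower bin), rescales observed
and simulated values identically by bin-median PRED over record PRED
(Bergstrand correction), and compares the observed 5th/50th/95th
percentiles with the band spanned by the pooled corrected simulated values
— by default their 2.5th--97.5th percentiles, i.e. a 95% prediction
interval for the concentrations themselves, not a confidence interval
around simulated percentiles. An observation is *outside* if its corrected
value falls strictly outside its bin's band; the percentage is reported to
one decimal with halves rounded away from zero (so 12/103 prints as
11.7%).

Records whose PRED is zero (possible when a lagged model is evaluated
against samples drawn inside its absorption window) cannot be
prediction-corrected and are excluded from the pcVPC with a warning; the
strict `prediction_correct()` primitive errors instead. A `max_time`
argument reproduces the common practice of omitting very late washout
samples (e.g. beyond 1000 h) — by default everything is counted.

## NPDE

`compute_npde()` centres each subject's observed vector on the simulated
mean and whitens observation and replicates with the inverse
lower-triangular Cholesky factor of the empirical simulation covariance
(decorrelation in record order). The pde is the rank of the whitened
observation among the whitened replicates over `K`, ties counted one half,
clamped to `[1/(2K), 1 - 1/(2K)]` to avoid infinite normal quantiles;
`npde = qnorm(pde)`. Subjects with a single observation use the scalar
standardisation path. Decorrelation is applied per subject *and analyte*:
the diagnostics are reported per analyte, and pooling both analytes into
one whitening would mix residual-error models with very different scales.

`npde_tests()` applies the standard battery — t-test of mean 0,
chi-squared (Fisher) test of variance 1, Shapiro--Wilk normality — with a
Bonferroni global verdict (reject if min p < alpha/3).

## Synthetic opportunistic cohorts

`generate_cohort()` emulates the structure of a standard-of-care pediatric
study so the whole pipeline is testable without clinical data: 62 subjects
by default; ages log-normal (median 4.67 y) truncated to 0.16--16.8 y;
weights from a piecewise log-linear growth curve with log-normal spread
truncated to 3.64--129 kg, preserving the age--weight correlation the
allometric models need without external growth-chart tables; doses per
subject log-normal (median 9, truncated 1--43) on jittered q12h/q24h
schedules; dose amounts median 0.017 mg/kg rounded to 0.05 mg increments;
samples per subject truncated-geometric (median 1, max 7); sampling times a
mixture of trough-like draws, uniform within-interval draws and a small
heavy-tailed fraction of late washout samples; LLOQ censoring at
0.100 ng/mL with BQL records flagged and the generating truth (class,
etas, noise-free concentrations) retained. The real study's
dosing-interval distribution is not published, so the q12h/q24h mix is an
exposed configuration default, not a claim.

What the generator does *not* emulate: ECMO and drug-interaction
physiology, CYP2D6 ontogeny, assay differences between studies, or
correlated covariate measurement (labs). Passing diagnostics on these
cohorts therefore demonstrates the statistical machinery under a known
generating process — it says nothing about any particular published
model's real-world validity.

## Calibration experiments and problem sizes

The test suite runs the battery at sizes chosen to balance Monte-Carlo
error against desk-scale runtimes:

* NPDE self-evaluation: 200 cohorts of 50 subjects, `K = 500`; the global
  Bonferroni rejection rate must land in [2%, 10%] at alpha 0.05 and the
  grand mean npde within ±0.1. These cohorts are generated with `lloq = 0`:
  self-evaluation presumes the diagnostic model is the true generating
  process, and censoring observations then excluding them would break that
  premise by selecting against low concentrations.
* Misspecification power: halving the generating clearance must be
  rejected in > 90% of 100 sixty-subject datasets, with positive mean
  npde (observations above the model's predictions).
* Mixture recovery: with 5-fold-separated class clearances and 7 samples
  per subject, the posterior-mode class is correct in > 90% of 200
  subjects.
* pcVPC self-evaluation: the pooled outside rate over 12 cohorts
  (~2800 records) must fall in [2.5%, 8%] — the nominal 5% plus binomial
  noise and the slight widening from a finite simulation band.
* The full five-model evaluation of a 62-subject cohort at `K = 1000`
  completes in a few minutes on one CPU and is byte-reproducible under a
  fixed seed.

## Known limitations

* Only linear cascades with a single oral depot are solved analytically;
  IV infusions, transit-compartment absorption, nonlinear clearance and
  enterohepatic recirculation are out of scope.
* No BQL likelihood handling (M3/M4): censored records are excluded, as
  they must be when none of the evaluated models modelled censoring.
* EBE-based diagnostics are reported without shrinkage correction; with a
  median of one observation per subject, eta shrinkage is substantial and
  class posteriors for sparsely sampled subjects stay close to the prior.
* The mixture-class posterior uses the MAP objective rather than the
  integrated likelihood; with well-separated classes the difference is
  negligible, with overlapping classes it sharpens posteriors slightly.
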