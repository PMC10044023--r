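---
title: "Methods: population PK and target attainment of ceftazidime on general wards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK and target attainment of ceftazidime on general wards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceftapk)
```

## The problem

Ceftazidime kills Gram-negative bacteria in a time-dependent fashion: what
matters clinically is the time plasma concentration spends above the
pathogen's MIC, not the peak. On general wards the accepted target is
concentration above the MIC for more than half of the first treatment day
(> 12 of the first 24 h), judged against the EUCAST *P. aeruginosa*
breakpoint of 8 mg/L, with a probability of target attainment (PTA) of at
least 90% across patients considered adequate. Because ceftazidime is
cleared almost entirely by the kidneys, guideline dosing steps down with
renal function: 2000 mg q8h for eGFR ≥ 50 mL/min/1.73 m², 1000 mg q12h
for 30–50, and 1000 mg q24h below 30, all as 0.5 h infusions. `ceftapk`
implements the complete analysis a prospective ward study of this question
needs: nonlinear mixed-effects estimation with covariate selection,
empirical Bayes individual endpoints, Monte Carlo PTA simulation, and the
model-qualification diagnostics, together with a synthetic-cohort
generator that stands in for patient-level data that cannot be shared.

## Structural model and variability

A one-compartment model with first-order elimination and zero-order
infusion input, parameterised by clearance `CL` and volume `V`:

$$CL_i = \theta_{CL}\left(\frac{eGFR_i}{76.86}\right)^{\gamma}
  \theta_{abx}^{\,abx_i} e^{\eta_{CL,i}}, \qquad
  V_i = \theta_V e^{\eta_{V,i}},$$

with observations under a proportional residual error,
$y_{ij} = f_{ij}(1 + \sigma\varepsilon_{ij})$. Random effects are
independent (diagonal) log-normals on CL and V; no inter-occasion
variability is active by default. Defaults are the final ward-model
estimates: $\theta_{CL}=3.74$ L/h at the reference eGFR of 76.86
mL/min/1.73 m², $\theta_V=21.8$ L, eGFR exponent $\gamma=0.75$,
concomitant-antibiotic factor $\theta_{abx}=1.56$, IIV 31.3 %CV (CL) and
40.2 %CV (V), proportional error 18.6 %. Two-compartment kinetics,
nonlinear elimination and protein-binding corrections are out of scope:
the analysis works in total concentrations (ceftazidime protein binding is
about 10%), and sparse ward sampling cannot support a peripheral
compartment anyway.

Two conventions circulate for converting a reported %CV to the log-normal
standard deviation $\omega$: `sd` takes $\omega = CV/100$ (the common
reporting shorthand) and `lognormal` takes
$\omega = \sqrt{\log(1 + (CV/100)^2)}$ (exact for a log-normal). Reports
rarely state which was used; `pop_params(cv_convention=)` supports both,
with `sd` the default. At 31.3 %CV the two differ by under 2% of the
value, well below any tolerance used here.

Because the profile between any two infusion starts/ends obeys
$dC/dt = R/V - k_e C$ with constant total rate $R$, every quantity the
analysis needs is closed-form: concentrations by superposition, window
AUCs by exact integration of each piecewise-exponential segment, and
time-above-MIC by inverting the segment exponential for its single
crossing (each segment is monotone, so no bisection fallback is ever
required; the analytic forms are verified against ODE, quadrature and
grid-scan oracles in the test suite). Units are fixed throughout: hours,
mg, L, mg/L, with time zero at the start of the first infusion.

## Dataset handling

Datasets use the common pharmacometric event-record CSV (`ID, TIME, EVID,
AMT, DUR, DV, BLQ` plus covariates). Two cleaning rules apply, in this
order: exact duplicate observation timepoints within a subject keep only
the first record, and below-LLOQ observations (LLOQ 0.1 mg/L) are imputed
at half the LLOQ, with any BLQ observation immediately following another
BLQ observation from the same subject removed as uninformative. The
combination is idempotent and never touches dose rows. Imputed BLQ values
enter estimation as ordinary observations (an M5-style treatment, matching
the imputation-based handling the design emulates) rather than through a
censored likelihood.

Renal function uses the standard published equations (CKD-EPI 2009 by
default, with the race-coefficient and 2021 race-free variants available
as options since the source laboratory's variant is not knowable; MDRD
and Cockcroft–Gault are provided as covariate-screen competitors). Renal
groups are half-open: adequate eGFR ≥ 50, moderate [30, 50), severe
< 30 — the boundary 50 belongs to the adequate group.

## Estimation

The marginal likelihood is Laplace-approximated: for each subject an inner
Newton optimisation (compiled code, finite-difference derivatives, step
damping) finds the posterior mode of $(\eta_{CL},\eta_{V})$, and the
log-determinant of the inner Hessian supplies the Laplace correction. The
outer optimisation over population parameters runs `nlminb` on
log-transformed scales (power exponents untransformed). Numerical choices
that matter:

* Inner optimisations restart from $\eta = 0$ at every outer evaluation,
  so the objective is a deterministic function of the parameters (warm
  starts made it path-dependent and noisy under finite differences).
* Predictions inside the proportional-error variance are floored at
  $10^{-4}$ mg/L and $\sigma^2$ at $10^{-8}$, keeping the likelihood
  defined in the degenerate noise-free limits the tests exercise.
* When the inner Hessian is not positive definite (a flat or saddle inner
  optimum), the Laplace determinant falls back to the prior-only curvature
  $1/(\omega_{CL}^2\omega_V^2)$. An earlier floor near zero effectively
  *rewarded* degeneracy with a large negative log-determinant and let the
  outer optimiser seek it out, visible as nested models with inconsistent
  objectives; the prior-curvature fallback removes the incentive.
* `nlminb`'s occasional "false convergence" on flat ridges is resolved by
  a derivative-free check: if Nelder–Mead cannot improve the objective
  from the candidate optimum, the point is accepted as converged.
* Standard errors come from the central-difference Hessian of the
  objective at the optimum; shrinkage is $1 - SD(\hat\eta)/\omega$.

Covariate analysis follows the conventional two-stage procedure: a
univariate screen of each candidate added alone to the base model
(objective drop ≥ 3.84, p < 0.05 on 1 df — the screen threshold is a
convention choice and configurable), then a joint multivariate fit with
backward elimination at a drop of ≥ 6.63 (p < 0.01 on 1 df) per retained
covariate. Continuous covariates enter as power functions normalised to
the dataset median (or a supplied reference), binary covariates as
multiplicative factors. The four renal markers (serum creatinine and the
three eGFR formulas) are near-duplicate measurements of one quantity; if
several pass the screen only the one with the largest drop is carried
forward, with ties broken by candidate order. On synthetic cohorts this
collinearity means the *retained renal marker* is occasionally a surrogate
of the generating one — the association is detected either way, and the
acceptance checks count it accordingly.

The bootstrap resamples subjects with replacement, stratified by renal
group so every replicate keeps the 25/10/5 case mix, refits, and reports
percentile 95% intervals; non-converged replicates are dropped and
counted, with a hard warning past 20%.

## Synthetic cohorts

`cohort_spec()`/`sample_cohort()` generate virtual cohorts with the ward
study's structure: 25/10/5 subjects in the three renal strata; per-stratum
eGFR drawn from a log-normal calibrated to the stratum median and IQR
(102.8 [78.1–124.8], 34.3 [30.9–48.2], 18.6 [10.6–25.9]) and truncated to
the stratum interval — the distribution family is a modelling choice, as
only location and spread are knowable; serum creatinine derived by
*inverting* the CKD-EPI equation given eGFR, age and sex, so all renal
markers are mutually consistent and realistically collinear; concomitant
antibiotic use at 19/25, 6/10, 2/5 prevalence; age, weight, height,
fever, ward and ethnicity from their stratum margins independently (their
only role is exercising the covariate screen's null behaviour — no joint
correlation structure is claimed, none being estimable from marginal
summaries). Dosing follows the guideline per stratum over 72 h. Two
protocol irregularities are injected by default because the emulated
design contains them: one severe-stratum subject dosed 2000 mg q24h
instead of 1000 mg q24h, and one adequate-stratum subject treated only
during the first 24 h.

Ward logistics shift follow-up administrations onto nurse rounds: with
probability 0.55 a subject's regimen gains an extra administration at the
next simulated 08:00 round after the first dose (first-dose clock time
uniform over 24 h), with subsequent doses interval-anchored on that round
and earlier nominal doses retained — giving *more* administrations in the
first day, which is the phenomenon of interest. Sampling is sparse: one
trough 0–15 min before a dose plus two random samples uniform between an
infusion end and the next dose, all within 72 h; 12.5% of subjects yield
only two samples. Observations carry proportional residual error and BLQ
flags below 0.1 mg/L.

What the generator does *not* emulate: real covariate correlations
(age–eGFR, weight–eGFR), assay error structure beyond proportional noise,
time-varying renal function, and non-adherence beyond the morning-round
shift. Passing tests therefore demonstrate internal consistency of the
pipeline under the stated design, not agreement with any particular
patient population.

## Target attainment and the Monte Carlo engine

Targets: the primary endpoint is > 12 h above MIC within 0–24 h (strict
inequality); secondary endpoints are ≥ 23.5 h above MIC within 0–24 h
(the first 0.5 h infusion makes a full 24 h unattainable, hence 23.5) and
> 12 h above MIC within 24–48 h. Attainment is evaluated on the
residual-error-free individual profile, the standard PTA convention. The
exclusion bookkeeping is explicit per-subject flags, not heuristics: the
mis-dosed subject stays in the primary endpoint (its attainment is robust
to halving the dose) but leaves all secondary endpoints; the 24 h-only
subject leaves the 24–48 h endpoints. Exposure comparisons use exact
AUCs over 0–24 and 24–48 h with Kruskal–Wallis tests across the three
renal groups.

`simulate_pta()` reproduces the dosing-simulation design: the cohort
under *exact* nominal intervals (q8h/q12h/q24h by group, administered
amounts kept — the mis-dosed subject simulates at 2000 mg), redrawing the
log-normal random effects for every subject in each of 1000 replicates;
fixed-effect uncertainty is not propagated, and residual error is excluded
from attainment. PTA is reported pooled over subject-replicates (the
per-replicate distribution is kept alongside, since a pooled and a
replicate-averaged summary can differ in principle).

When the simulation source is a cohort specification rather than a real
dataset, the covariate design is built to match the stated margins rather
than to add sampling noise the emulated design never had: the per-stratum
eGFR values are a jittered systematic (quantile-stratified) sample of the
calibrated log-normal, drawn once and held fixed, while the binary
assignments — which subjects carry the antibiotic flag at the exact
prevalences, and which severe subject carries the mis-dose — are redrawn
each replicate. A single fixed random assignment makes the small severe
stratum's PTA an arbitrary function of the seed (the 50 possible
assignments span several percentage points); marginalising reports the
expectation over the unobserved assignment instead. With a real dataset
as source, observed covariates are simply held fixed.

`compare_shift_vs_exact()` isolates the morning-round effect: the same
individual parameters evaluated under the administered (shifted) and the
exact-interval regimen, paired per subject.

## Diagnostics

The prediction-corrected VPC normalises observations and simulations by
the bin-median population prediction, bins quantile-wise on time after the
most recent dose (default 6 bins, bins under 5 observations merged into a
neighbour — the binning is a design choice, nothing in the emulated
design prescribes one), and compares observed 5th/50th/95th percentile
curves with 95% bands from (by default) 1000 simulated replicates.
Goodness-of-fit tables report population and individual predictions,
proportional-error-weighted residuals, and log-scale bias/RMSE.

## Problem sizes used by the checks

The packaged verification suite runs at sizes chosen to make each
property measurable with clear margins: oracle-equivalence and invariant
suites on 100 randomised parameter/regimen instances; parameter recovery
and covariate retention on 20 replicate cohorts at the default truth;
null-covariate false-retention on 30 cohorts generated without covariate
effects (about 330 candidate decisions against the ~1% nominal rate);
VPC calibration on 20 self-simulated repeats at 500 simulations each; the
Monte Carlo PTA reproduction at the full 1000 replicates.

## Known limitations

* The Laplace approximation with three samples per subject estimates the
  variance components with limited precision; IIV recovery tolerances are
  accordingly wide (40% relative), and shrinkage is substantial.
* The eGFR reference 76.86 mL/min/1.73 m² is treated as an opaque
  constant of the final model; nothing identifies whether it is a cohort
  mean or median.
* The generator's marginal-only covariate structure means covariate-screen
  behaviour on real, correlated data may differ from the null behaviour
  tested here.
* Inter-occasion variability is not implemented: the final emulated model
  excludes it, three samples per subject over 72 h cannot inform
  occasion-level effects, and carrying occasion-level random effects
  through the inner Laplace optimisation would complicate the estimator
  for a component the analysis never activates.
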