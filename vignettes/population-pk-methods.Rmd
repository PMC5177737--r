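---
title: "Population PK modeling and Bayesian forecasting of clotting factor concentrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK modeling and Bayesian forecasting of clotting factor concentrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemopk)
```

## The problem

Prophylaxis in hemophilia A and B keeps plasma factor VIII or IX activity
above a protective threshold (conventionally 0.01--0.05 IU/mL, where
1 IU/mL is 100% of normal) by regular intravenous infusions of a factor
concentrate. Pharmacokinetics differ markedly between patients of similar
age and weight, so dosing tailored to the individual requires individual
PK estimates — classically an 11-sample study (four samples in the first
hour, seven more out to 48 h for FVIII or 72 h for FIX), which is
impractical in routine care and nearly impossible in children.

Population pharmacokinetics (PopPK) resolves this tension. A hierarchical
nonlinear mixed-effects model, estimated once on rich (densely sampled)
data for a given concentrate brand, quantifies the typical kinetics, the
between-subject variability (BSV) and the residual assay noise. Frozen as
an informative prior, that model lets a Bayesian step recover an
individual patient's parameters from as few as 3--4 sparse samples, and
report the times at which the factor level is expected to cross the
clinical thresholds, with credibility intervals that honestly reflect how
much the estimate leans on the individual's data versus the population.

`hemopk` implements that entire workflow: dataset assembly and checking
in the NONMEM-dialect CSV layout, closed-form structural models,
Laplace/FOCEI-class population estimation with M3 censored likelihood,
covariate model building, model evaluation, and individual forecasting.

## The dataset dialect

Datasets are comma-separated event records with the conventional columns
(`CID`, `OCC`, `TIMEH`, `AMT`, `RATE`, `DV`, `AGE`, `BW`, `EVID`, `DOSE`,
`PREDOSE`, `MDV5`, `BASELINE`, `BLQ`, `MDV3`, plus optional `HT`, `VWF`,
`RACE`, `BTYPE`, `HCT`). For each subject the first record (time zero)
carries the pre-dose level and the endogenous baseline; when no baseline
was measured, 0.005 IU/mL (0.5% of normal, 5 IU/L) is assumed, the
conventional midpoint of the severe range. The second record is the dose:
`TIMEH` holds the infusion duration in hours *truncated* (not rounded) to
four decimals — a 10-minute infusion is `0.1666` — and `RATE = AMT/TIMEH`.
Later records are observations; a sample below the limit of
quantification (LOQ, default 0.01 IU/mL = 10 IU/L, also the defining
level of severe hemophilia) is stored as an `EVID = 3` BLQ row with
`MDV3 = 0` (it enters the censored likelihood) and `MDV5 = 1` (it is
excluded from residual-based diagnostics).

Concentrations are handled internally in IU/L (the `DV` unit);
user-facing thresholds quoted in IU/mL are converted by a factor of 1000
at the interface, so no mixed-unit arithmetic occurs inside the engine.

For multi-occasion data the single-occasion record pattern repeats; we
adopt the convention that every dose record's `TIMEH` is the absolute
end-of-infusion time, so that infusion start = `TIMEH - AMT/RATE`. For
occasion one this reduces exactly to the standard layout.

**Data checking.** `validate_pk_dataset()` flags rising post-infusion
concentrations, missing values, implausible continuous covariates,
unexpected categorical codes, and duplicate records; flags must be
explicitly resolved (corrected or excluded, with an audit log) before
analysis — flagged rows are never silently kept. The rising-concentration
rule takes a `rise_tolerance` argument: the default 0 flags *any* rise
for human review, which is the conservative bookkeeping rule; when
screening data whose assay error is known (for instance simulated
cohorts, where a ~10% CV makes small rises routine), a tolerance of 0.5
suppresses flags that measurement noise fully explains. The pipeline's
automated validation stage uses 0.5 for exactly this reason.

## Structural models

Disposition is linear 1-, 2- or 3-compartment with constant-rate IV
infusion, parameterized by clearances and volumes (`CL, V`;
`CL, V1, Q, V2`; `CL, V1, Q2, V2, Q3, V3`). The rate constants
$\lambda_i$ and unit-bolus coefficients $A_i$ come from an
eigen-decomposition of the micro-constant matrix (numerically stable near
degenerate rate constants; exact ties are perturbed by a relative
$10^{-9}$), and the concentration under an infusion of rate $R$ started
at $t_0$ is

$$C(t) = \text{baseline} + \sum_i \frac{R\,A_i}{\lambda_i}
  \left(1 - e^{-\lambda_i (t - t_0)}\right)$$

during the infusion, with the standard cessation superposition
afterwards; multiple doses superpose. The endogenous baseline is additive
and constant — it is not a compartment — which matches how factor levels
plateau at the patient's endogenous production. A measured pre-dose level
above baseline is represented as an initial central-compartment amount
$(\text{PREDOSE} - \text{BASELINE}) \times V_1$ that decays according to
the model; this is the simplest mechanistic reading of "residual factor
from a previous dose", and a constant-subtraction alternative was
deliberately not chosen because it would violate mass balance at late
times.

Closed forms are verified in the test suite against an independent
adaptive ODE integrator (deSolve) to a relative error below $10^{-6}$
over randomized parameter sets for all three compartment counts.

## The hierarchical model

Individual parameters are log-normal around covariate-adjusted typical
values,

$$\theta_{ij} = TV(\theta_i)\, e^{\eta_{ij}},\qquad
  \eta_j \sim N(0, \Omega),$$

with $\Omega$ diagonal during model development and optionally
unstructured to test for correlated random effects. Covariate effects on
a typical value use the standard forms — linear
$TV(1+\theta_V(x-c))$, power $TV(x/c)^{\theta_V}$, exponential
$TV e^{\theta_V (x-c)}$, and categorical $TV(1+\theta_V 1\{x=l\})$ —
centered at the dataset median (frozen into the model object so that
forecasting never re-derives centering from new data). Multiple effects
on one parameter compose multiplicatively, which preserves positivity.

Residual error supports additive, proportional, exponential
(implemented as additive error on log-concentration), and the combined
additive-proportional form $g(f)=\sqrt{f^2\sigma_{prop}^2 +
\sigma_{add}^2}$, the common default in PK modeling.

## Estimation

The population fit maximizes a Laplace approximation to the marginal
likelihood, the same family as FOCE with interaction: for each subject
the joint $-2\log$ likelihood in $\eta$,

$$j(\eta) = \sum_{\text{valid}} \left[\frac{(y-f)^2}{g^2} + \log 2\pi
  + 2\log g\right] - 2\sum_{\text{BLQ}} \log\Phi\!\left(\frac{LOQ -
  f}{g}\right) + \eta'\Omega^{-1}\eta + \log|2\pi\Omega|,$$

is minimized by a Newton search started at $\eta = 0$ (deterministic;
gradient tolerance $10^{-6}$), and the subject's contribution is
$j(\hat\eta) + \log\det(H/4\pi)$ with $H$ the curvature of $j$ at the
mode. Because $g$ is evaluated at the individual prediction, the
eta-sigma interaction is retained. BLQ records contribute the M3
censored-likelihood terms $\Phi((LOQ - f)/g)$ rather than being dropped
or imputed at LOQ/2. The outer optimizer is a bounded quasi-Newton
(`nlminb`) over log typical values, raw covariate coefficients, the
log-Cholesky factor of $\Omega$ (guaranteeing positive
semi-definiteness) and log sigmas, with up to three polishing restarts; a
restart that finds no material improvement counts as converged, since
`nlminb` reports "false convergence" at optima of objectives carrying
slight inner-optimization noise. The likelihood kernel is compiled
(Rcpp/RcppArmadillo), which is what makes the replicated simulation
experiments below affordable.

The approximation is validated, not assumed: on 1-eta models the Laplace
OFV is checked against adaptive numerical integration of the marginal
likelihood (agreement well within 0.1 OFV units), and the degenerate case
$\Omega \to 0$ is checked against the naive pooled fit.

**Model building.** Development follows the conventional path: naive
pooled exploration of compartment count, OFV-based comparison of nested
models (a decrease of 3.84 or more per added parameter, the 0.95
chi-squared quantile quoted at two decimals, so a drop of exactly 3.84
qualifies; more added parameters use the corresponding chi-squared
quantile), diagonal-vs-unstructured $\Omega$ comparison, and stepwise
forward covariate inclusion. A candidate covariate must both clear the
OFV criterion and have a 95% Wald confidence interval for its
coefficient excluding zero ("precision" operationalized, since the
protocol names the criterion without a formula). A stricter backward
pass (default 6.63, the 0.99 quantile) is available but off by default
and labeled an extension. Eta-covariate screening ranks associations by
Pearson correlation (continuous) or Kruskal-Wallis statistics
(categorical codes) to propose candidates.

Because clinicians are only guaranteed to supply age and weight, several
model variants per concentrate can be kept in a registry with a
preference ranking; `select_model_variant()` picks the best variant whose
required covariates are available, and the registry refuses to be built
without an age/weight-only fallback.

## Evaluation

`compute_diagnostics()` emits plot-ready tables (no rendering): observed
versus population/individual predictions, conditional weighted residuals
(CWRES, the FOCE first-order construction about the conditional mode:
$E[y] \approx f(\hat\eta) - F\hat\eta$, $V = F\Omega F' + \text{diag}(g^2)$,
residual $V^{-1/2}(y - E[y])$), IWRES, QQ data, eta histograms,
eta-shrinkage $(1 - SD(\hat\eta_k)/\omega_k)\times 100$ and
epsilon-shrinkage $(1 - SD(\text{IWRES}))\times 100$ (the SD-based
variants), the condition number of the estimation correlation matrix, and
covariate variance inflation factors. Bootstrap stability uses
subject-level resampling with percentile intervals; non-converged
resamples are excluded from percentiles and counted, and a success rate
below 50% flags the model unstable. Cross-validation partitions
*subjects* (holdout, default 20%, or k-fold, default 5 — both left open
by the protocol "depending on the size of the dataset") and scores
population-level predictions (eta = 0) for held-out subjects by mean
error and mean squared error on the concentration scale (a log-scale
switch is provided; concentration scale is the default because the
clinical thresholds live there). Held-out predictions are population
level because a held-out subject contributes no data to condition eta;
the sparse-conditioned alternative is exactly what
`sparse_subset_validation()` measures: MAP forecasts (terminal half-life,
times to 50/20/10 IU/L) from a 3--4 point subset versus the full rich
profile, per subject.

## Bayesian forecasting

`map_individual()` finds the conditional eta mode under the frozen
population priors — the same code path as the population fit's inner
problem, honoring PREDOSE, BASELINE and BLQ rules identically.
`posterior_band()` draws from the posterior using a Laplace proposal
(normal at the MAP with covariance $2H^{-1}$) re-weighted by importance
sampling against the exact joint; sampler identity is not the claim —
the distributional behavior is what the tests pin down (zero-data
forecasts reproduce the prior predictive; bands contract monotonically
as samples are added; with $\Omega \to 0$ the forecast collapses to the
population-typical curve). The credibility band is on the underlying
factor level — residual assay error is deliberately excluded, matching
how smooth forecast bounds are read clinically — with an option to add a
predictive (assay-inclusive) band.

Reported quantities follow the clinical reporting convention: for each
threshold (0.05, 0.02, 0.01 IU/mL) the time at which the *lower* 95%
credibility bound first reaches it — conservative by construction —
refined to better than 0.1 h, searched only after the end of the last
infusion; and the lower/median/upper concentrations at 24, 48 and 72 h.
If the lower bound has not crossed by the end of the reporting grid
(0 to max(96 h, 5 terminal half-lives) at 0.25 h resolution), the search
extends the horizon geometrically rather than extrapolating a fitted
curve, because every posterior draw provably decays toward baseline;
"beyond horizon" is reported only when a threshold does not exceed the
baseline. `solve_regimen()` closes the loop for dose planning: given two
of dose, interval and target trough at steady state, it returns the third
(dose is linear in trough-above-baseline; interval by monotone root
finding; a target at or below baseline is reported as "achieved without
dosing" rather than as a numerical answer).

## The synthetic cohort generator

No public dense datasets exist for these concentrates, so the test bed is
a simulator with known ground truth. Its defaults describe a plausible
recombinant-FVIII-like study — *implementation defaults, not estimates of
any real brand*: 1-compartment, CL 0.17 L/h and V 3 L (terminal half-life
about 12 h), log-normal BSV with $\omega^2 = 0.09$ on CL and V, combined
error ($\sigma_{add}$ = 2 IU/L, $\sigma_{prop}$ = 0.1), ages uniform on
12--65 years with weight following a two-segment growth curve (linear
rise to 18 years, adult plateau near 73 kg, log-normal spread 15%,
spanning roughly 42--130 kg), 50 IU/kg infused over 10 minutes, an
11-sample rich schedule (0.25--1 h x4, then 3--48 h x7), and censoring at
the 10 IU/L LOQ. `sparsify()` reduces rich cohorts to clinical-style 3--4
sample designs; `inject_errors()` plants known defects to exercise the
validation rules (planted rises double the preceding value so they are
unambiguous at any reasonable tolerance).

What the simulator does *not* emulate — assay-to-assay differences,
inter-occasion variability (the protocol treats within-subject
variability as small relative to BSV and we follow it), time-varying
covariates, model misspecification of the disposition itself — bounds
what green tests prove: they establish the engine's internal correctness
and statistical calibration under the stated generating conditions, not
the clinical adequacy of any particular brand model.

## Study designs used in the replicated experiments

The simulation experiments in the tests and the acceptance script use
problem sizes chosen to estimate each property with useful precision
while keeping a full run in minutes:

* **Parameter recovery**: 40 subjects x 11 samples, $\omega^2=0.09$,
  proportional $\sigma=0.1$. With $\omega=0.3$ the standard error of the
  mean eta is $\approx 4.7\%$, so the 10% bias check is a two-sigma
  criterion; the fitted typical values track the realized mean eta of
  each cohort almost exactly.
* **M3 versus BLQ exclusion**: 50 paired replicates of a washout-focused
  design (20 subjects sampled at 36--96 h, 60 IU/kg, proportional
  $\sigma=0.2$) giving roughly 20% BLQ records at the 10 IU/L LOQ.
  Sampling concentrates where profiles cross the LOQ because that is
  where informative censoring acts. Bias is measured against each
  cohort's realized geometric-mean clearance, which removes the shared
  finite-sample noise of the eta draws from both arms of the pairing.
* **LRT calibration**: 200 null replicates (12 subjects x 6 samples) of
  adding a spurious weight-on-clearance power term; the rejection rate at
  the 3.84 criterion is compared with the 5% nominal level within its
  binomial band. The spurious-covariate fit warm-starts at the base
  optimum so that any OFV drop is attributable to the added term.
* **Forecast behavior**: 20 paired subjects for the 2-versus-6-sample
  band-contraction check, 500--4000 importance draws depending on the
  tolerance of the comparison.

## Numerical choices and edge cases

* Inner Newton: finite-difference gradient/Hessian (step $10^{-4}$),
  ridge-stabilized steps with backtracking, start at 0, tolerance
  $10^{-6}$; non-convergence flags the subject and the fit.
* Outer optimizer bounds (log scale, +-20) prevent runaway parameters;
  an exactly interpolating model (zero residuals) is caught by the bound
  rather than diverging.
* Truncation to four decimals applies to all `TIMEH` values at assembly,
  reproducing the dialect's printed convention.
* Importance weights are normalized in log space; the effective sample
  size is reported, and a degenerate posterior curvature falls back to
  prior sampling with a warning instead of failing.
* Weighted quantiles interpolate the cumulative-weight function; the
  band-ordering invariant (lower <= median <= upper) holds pointwise by
  construction.
* `time_to_level()` exploits that post-infusion profiles are sums of
  positive decaying exponentials, hence strictly decreasing: the first
  crossing is the unique one, bracketed then refined by `uniroot` to
  better than 0.01 h.

## Known limitations

Estimation is Laplace/FOCEI-class, not stochastic (no SAEM or importance
sampling estimators), and no NONMEM control files are read or written:
the YAML model artifact is the equivalent interface. Inter-occasion
variability is not modeled. The exponential residual form drops the
constant Jacobian of the log transform from its OFV, so its OFV values
are comparable between models on the same data but not with other error
forms. Standard errors are Wald-type from the numerical information
matrix; the bootstrap is the recommended check when they matter.
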