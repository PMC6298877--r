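---
title: "Joint models for drug response and time to side effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint models for drug response and time to side effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brjoint)
```

## The scientific question

When a drug's side effects arise from its primary pharmacological
action, the patients who respond best may also be the ones most at
risk. In type 2 diabetes the benefit is glycemic response — the fall in
HbA1c (%) from its pre-treatment baseline — measured repeatedly at trial
visits, while each side effect (gastrointestinal events, hypoglycemia,
edema, fracture) is a time-to-first-event outcome. brjoint estimates the
association between the two processes with shared-random-effects joint
longitudinal–survival models, alongside the two simpler estimators that
an analyst would otherwise reach for.

Throughout, "response" is on the response-positive convention:
`response = baseline HbA1c − current HbA1c`, so a 1% greater response
means one percentage point more glucose lowering, and every reported
hazard ratio is per 1% greater absolute response. (The raw visit-minus-
baseline change is available via
`compute_response(convention = "change_from_baseline")`.)

## The model

**Longitudinal submodel.** The observed response of subject $i$ at time
$t$ (years since randomization) is
$$y_i(t) = m_i(t) + \varepsilon_i(t), \qquad
\varepsilon_i(t) \sim N(0, \sigma^2),$$
$$m_i(t) = \beta_0 + \beta_1 N_1(t) + \beta_2 N_2(t)
 + \beta_3 \,\text{BaselineHbA1c}_i + b_{i0} + b_{i1} N_1(t)
 + b_{i2} N_2(t),$$
where $N_1, N_2$ are a natural cubic spline basis of time with one
internal knot at the pooled median observed measurement time, included
in both the fixed and the random parts, and
$b_i \sim N(0, D)$ with unstructured $D$. The basis is *anchored*: every
basis function vanishes at $t = 0$, so the statement "response is zero
at randomization" is carried entirely by the intercept terms, and the
basis is linear beyond its boundary knots (the natural condition),
giving well-behaved evaluation at event times beyond the last
measurement.

**Survival submodel.** The hazard of the first side effect is
$$h_i(t) = h_0(t)\, \exp\{\gamma_0\,\text{BaselineHbA1c}_i
 + \alpha\, f(m_i, t)\},$$
with $f(m_i, t) = m_i(t)$ for the *current-value* association (JMcv) and
$f(m_i, t) = \int_0^t m_i(s)\,ds$ for the *cumulative* association
(JMcum). Because $m_i$ is a spline, the cumulative integral is an exact
piecewise-quartic antiderivative (`ncs_antiderivative()`); no inner
quadrature is ever used, and the synthetic-data generator uses the same
antiderivative, so simulation and estimation share one definition of
cumulative exposure. The log baseline hazard $\log h_0(t)$ is an
unpenalized cubic B-spline with five internal knots at the sextile
quantiles of observed event times and boundary knots at 0 and the
longest follow-up.

**Comparators.** Model 3 (LOCF) carries the *observed* response forward
between measurements as a time-dependent covariate in a Cox model on
counting-process intervals; it ignores measurement error, which biases
its association toward zero (regression dilution). Model 4 (6-month
landmark) uses the single response value measured nearest 6 months
(window ±45 days, ties to the earlier measurement) as a fixed exposure
in a Cox model with delayed entry at 6 months. Both adjust for baseline
HbA1c, and both are fitted on the partial likelihood via the survival
package (Efron ties by default; Breslow available).

## Estimation

The joint likelihood integrates, per subject, the product of the
Gaussian longitudinal density, the proportional-hazards density and the
random-effects density over $b_i$. Numerical choices:

* **Random-effects integral: pseudo-adaptive Gauss–Hermite.** Nodes are
  centered and scaled once at each subject's empirical-Bayes posterior
  from the initial longitudinal ML fit, then held fixed, with 7 nodes
  per dimension by default (343 tensor nodes for the spline random
  effects). Fixing the rule keeps the objective smooth and makes the
  analytic score (implemented in C++) the exact gradient of the
  approximated objective; re-centering each iteration would make the
  quadrature rule parameter-dependent and the gradient inconsistent
  with it. Adequacy is enforced by tests: the subject likelihood
  matches a dense 200-nodes-per-dimension brute-force integral to
  1e-5 relative, and doubling the node count changes it by less than
  1e-6.
* **Cumulative hazard:** 15-node Gauss–Legendre on $(0, T_i)$; the
  integrand is smooth because the trajectory (or its exact integral)
  is polynomial between knots.
* **Optimization:** ML throughout (not REML), so the standalone
  longitudinal fit, the survival-only stage and the joint fit are on
  one likelihood scale. $D$ is parameterized by its log-diagonal
  Cholesky factor (positive semi-definiteness by construction),
  $\sigma$ on the log scale. The fit starts from the longitudinal ML
  estimates, then fits the survival block alone with empirical-Bayes
  plug-in trajectories, then maximizes everything jointly by BFGS with
  the analytic score. The optimum is checked to dominate the two-stage
  start (an ascent test runs in the suite). The longitudinal fit
  itself profiles the fixed effects out by GLS and optimizes only the
  variance parameters, with an analytic gradient via the envelope
  theorem; subjects sharing a visit-time pattern share one marginal
  covariance factorization.
* **Convergence fallback.** If the spline-random-effects fit does not
  converge, the model is refitted with a linear random time slope
  (`linear_re`) — random intercept and slope, spline fixed effects —
  and the downgrade is recorded on the fit and in run logs. Because
  the first basis function is exactly $t$, the linear variant is nested
  in the spline variant, which the suite verifies through the
  likelihood ordering.
* **Inference.** Wald only: the covariance is the inverse negative
  Hessian at the optimum, obtained by forward-differencing the
  analytic score (more accurate than differencing the likelihood twice
  at the same cost). SEs for the fixed effects, $\gamma_0$, $\alpha$
  and the baseline-hazard coefficients are read off directly; the
  residual-variance SE is delta-method-mapped from the log scale.
  Hazard ratios are $\exp(\hat\alpha)$ with
  $\exp(\hat\alpha \pm z_{1-\alpha/2}\,\text{SE})$ intervals.

## The synthetic trial generator

Real individual-participant data from the motivating 5-year
head-to-head trial are access-controlled, so the package ships a
generator (`sim_config()`, `generate_cohort()`) whose defaults were
chosen once to emulate that design and are used as the study conditions
for every statistical test in the suite:

* **Design:** post-baseline visits every 2 months in year 1, then every
  3 months to 5 years (22 scheduled visits); administrative censoring
  at 5 years; independent exponential withdrawal at rate 0.2/year,
  giving a median follow-up near 2.9 years. Visits continue after a
  side effect (adverse events did not end trial follow-up); downstream
  eligibility and censoring rules decide what enters each model.
* **Baseline HbA1c:** normal, mean 7.3%, SD 0.9%, truncated to
  [6, 10] — matching a median of 7.3% with interquartile range roughly
  6.7–7.9%.
* **Trajectory:** mean latent response rises to about 1.3% at its
  2.5-year nadir of HbA1c and relaxes to 0.5% by year 5 (glycemic
  drift); between-subject response SD grows from ≈0.35% at year 1 to
  ≈0.9% at year 5; residual SD 0.35%.
* **Hazard:** constant baseline rates calibrated once by n = 5,000
  Monte Carlo so the preset event fractions land near 37%, 26%, 13%
  and 7% — the frequency ladder of GI events, hypoglycemia, edema and
  fracture — with `gamma0 = 0.18` and association `alpha = 0.35`
  (current) or `0.15` (cumulative) on the response-positive scale. The
  `sim_config()` default uses the 26% calibration.
* **Extras for the filtering rules:** severity labels drawn
  multinomially (0.46/0.46/0.08 mild/moderate/severe, so that about
  half of events are moderate-plus and 8% severe), and a pre-trial
  history flag with probability 0.06 to exercise the edema exclusion.

Event times invert each subject's cumulative hazard exactly
(quadrature plus bracketed root finding; the suite checks
$H_i(T) = -\log U$ to 1e-8), so the generator makes no proportional-
hazards shortcut.

**What the generator does not emulate.** Withdrawal is independent of
the response trajectory, whereas the real trial censored at glycemic
failure — an outcome-dependent mechanism that could induce informative
censoring; visit attendance is perfect up to withdrawal; severity labels
are independent of everything else; and there is one side-effect type
per cohort. Passing tests therefore demonstrate correctness of the
estimators under a faithful but idealized trial, not robustness to
informative dropout or recording bias in real data.

## Problem sizes used by the test suite

The statistical properties are checked at sizes chosen to give stable
Monte-Carlo behaviour at desk scale: association recovery uses 20
seeded cohorts of n = 500 for each parameterization (current truth
0.35, tolerance ±0.05 on the replicate mean; cumulative truth 0.15,
±0.03); null calibration uses 50 cohorts of n = 300 with the 5% Wald
test expected to reject in at most 15% of replicates for both JMcv and
LOCF; the attenuation property (|LOCF estimate| < |JMcv estimate| in at
least 80% of replicates) uses 20 cohorts of n = 300 with residual SD
0.5% and truth 0.5. Oracle checks (dense-grid quadrature, risk-set
enumeration, trapezoid integrals, GLS and nlme cross-fits) run on small
fixed cohorts in seconds.

## Design notes and open choices

* The source trial's analysis software reports HRs per 1% greater
  response; with response defined as visit-minus-baseline change the
  sign of the association coefficient is ambiguous. The package
  resolves this by convention, not guesswork: all internal fitting is
  on the response-positive scale, so $\exp(\alpha)$ is per 1% greater
  response by construction.
* The trajectory knot sits at the 50th percentile of pooled observed
  measurement times (the standard mixed-model convention) rather than
  of per-subject follow-up ends.
* The baseline-hazard B-spline is unpenalized; with five internal knots
  at event-time quantiles each inter-knot region contains events by
  construction, which keeps the coefficients identified.
* Under a severity sensitivity filter, non-qualifying events are
  recoded as censoring at the event time rather than extending
  follow-up — conservative, and avoids using post-event measurements.
* The landmark window is ±45 days around 6 months with the nearest
  measurement winning (earlier on ties).
* Orchestration is exposed as plain functions (`run_analysis()`,
  `run_specificity_grid()`) returning provenance-stamped tibbles; being
  an analysis library, the package deliberately ships no shell
  executable.

## Known limitations

Single side-effect type per analysis (no recurrent events, no competing
risks); association structures limited to current value and cumulative
value (no slope, recency-weighted, or time-varying association);
scalar iid residual variance; Wald inference only; no penalization or
knot selection for either spline.
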