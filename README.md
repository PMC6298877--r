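# brjoint

Benefit–risk joint models for drug therapy: shared-random-effects joint
longitudinal–survival models linking a biomarker response trajectory
(change from baseline in HbA1c, %) to the time to a first drug side
effect, together with the two standard comparators — a
last-observation-carried-forward (LOCF) time-dependent Cox model and a
6-month landmark Cox model with delayed entry.

The package is for biostatisticians and pharmacoepidemiologists asking
whether the patients who benefit most from a drug are also the ones at
greatest risk of its side effects — the core trade-off of any precision
medicine strategy.

## The model

For subject *i*, the observed response at trial time *t* (years) is
`y_i(t) = m_i(t) + e_i(t)` with

```
m_i(t) = β0 + β1 N1(t) + β2 N2(t) + β3 BaselineHbA1c_i
         + b_i0 + b_i1 N1(t) + b_i2 N2(t),      b_i ~ N(0, D)
```

where `N1, N2` is a natural cubic spline of time (one internal knot,
anchored so all basis functions vanish at randomization). The side
effect hazard shares the subject's latent trajectory:

```
h_i(t) = h0(t) exp{ γ0 BaselineHbA1c_i + α f(m_i, t) }
```

with `f(m_i, t) = m_i(t)` (current-value association, "JMcv") or
`f(m_i, t) = ∫0^t m_i(s) ds` (cumulative association, "JMcum", exact
spline antiderivative). `log h0(t)` is a cubic B-spline with five
internal knots. All parameters are estimated simultaneously by maximum
likelihood (pseudo-adaptive Gauss–Hermite quadrature over `b_i`,
analytic score in C++), and `exp(α)` is reported as the hazard ratio
per 1% greater absolute HbA1c response. Real trial data being
access-controlled, a synthetic-cohort generator reproduces the trial's
design (bimonthly visits in year 1 then quarterly to 5 years, baseline
HbA1c centered at 7.3%) with known ground truth.

## Worked example

Simulate an ADOPT-like cohort with a true current-value association of
0.35, prepare it, and compare the joint model with the LOCF Cox model:

```r
library(brjoint)

cfg <- sim_config(n_subjects = 600, alpha = 0.35, seed = 2026)
cohort <- generate_cohort(cfg)
cohort
#> <br_cohort> 600 subjects, 8576 measurements, 143 events (23.8%)

cohort <- apply_censoring(cohort, admin_time = 5)
elig <- apply_eligibility(cohort)      # needs a pre-event measurement
elig$exclusions
#> # A tibble: 2 × 2
#>   reason                   n
#>   <chr>                <int>
#> 1 pre_trial_history        0
#> 2 no_pre_event_measure    37

fit <- fit_joint_model(elig$cohort, jm_spec("current"))
fit
#> <br_jm_fit> current association, spline_re, 563 subjects / 129 events, logLik -4136.15
#>   alpha (log HR per 1% greater response): 0.5151 (SE 0.1970)
#>   gamma0 (log HR per 1% baseline HbA1c): 0.2194

hazard_ratio_report(fit)
#> # A tibble: 1 × 9
#>   model term        hr conf_low conf_high       p     n n_events converged
#> 1 jmcv  response  1.67     1.14      2.46 0.00894   563      129 TRUE

locf <- fit_locf_cox(build_counting_process(elig$cohort))
hazard_ratio_report(locf)
#> # A tibble: 1 × 9
#>   model term        hr conf_low conf_high       p     n n_events converged
#> 1 locf  response  1.52     1.13      2.04 0.00531   563      129 TRUE
```

The joint-model hazard ratio (1.67 per 1% greater response) exceeds the
LOCF one (1.52): the LOCF covariate carries measurement error, which
dilutes its association toward the null, while the joint model
estimates the latent, error-free trajectory. `hazard_ratio_report()`
rows from all models share one format, so `run_analysis()` can emit a
side-by-side comparison table, and `run_specificity_grid()` crosses
every scenario preset with every model. `tidy()`, `glance()` and
`autoplot()` methods are available for all fitted objects.

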