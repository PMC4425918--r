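# dynjm — joint models and dynamic event prediction for serial biomarkers

`dynjm` is an R package for biostatisticians and cardiovascular
researchers who follow patients longitudinally — the motivating setting is
severe aortic stenosis, where brain natriuretic peptide (BNP, pg/ml) is
assayed at roughly half-yearly visits and two endpoints matter: death and
aortic-valve intervention.  The package couples a linear mixed-effects
model for the biomarker with relative-risk survival models through shared
random effects, and turns the fitted joint model into *dynamic*,
subject-specific predictions that are revised every time a new measurement
arrives.

## The model

For subject *i*, log BNP follows a linear mixed model

y_i(t) = x_i(t)'β + b_{0i} + b_{1i} t + ε,  b_i ~ N(0, D),  ε ~ N(0, σ²),

with fixed effects for time (years), aortic valve area (cm²), age,
symptoms, gender, and SD-scaled LV ejection fraction and creatinine.  The
hazard for one outcome depends on the *current* trajectory value
m_i(t) = x_i(t)'β + b_{0i} + b_{1i} t:

h_i(t | b_i) = h_0(t) · exp{ γ'w_i + α · m_i(t) },

with a Weibull baseline h_0.  Death and intervention get separate joint
models, each estimated by full maximum likelihood with pseudo-adaptive
Gauss–Hermite quadrature over the random effects (RcppArmadillo kernel).
From a fitted model, the event-free probability

π(u | t) = P(T* ≥ u | T* > t, measurements up to t)

is computed by a Monte-Carlo estimator with parameter and random-effect
uncertainty (or a deterministic first-order quadrature mode), and
discrimination is assessed by time-dependent ROC/AUC with subject-level
bootstrap refitting.  A cohort simulator with trajectory-linked hazards
generates synthetic data with the study's structure (191 subjects, visits
at 0/0.5/1/2 years, ~15% deaths, ~48% interventions over ≤2.5 years), so
the whole pipeline is testable without any patient-level data.

## Worked example

```r
library(dynjm)
cohort <- preprocess_cohort(simulate_cohort(default_truth(), 191, seed = 20))
fit <- fit_joint(cohort, "death")
fit
#> Joint model fit (outcome: death)
#>   subjects 191, events 19, logLik -636.473, GH nodes 15 (adaptive)
#>   Weibull baseline: shape 1.095, scale 387.831
#>                term   coef   HR    se      p
#> 1 value_log_current  0.919 2.51 0.272 0.0007
#> 2               ava -2.513 0.08 1.504 0.0946
#> 3               age -0.006 0.99 0.026 0.8261
#> 4              male  0.305 1.36 0.500 0.5420
#> 5          symptoms  0.816 2.26 0.662 0.2174
#> 6       lvef_scaled -0.023 0.98 0.247 0.9249
#> 7 creatinine_scaled  0.042 1.04 0.184 0.8209
```

The `value_log_current` row is the association: on this simulated cohort a
one-unit rise in current log-BNP multiplies the death hazard by 2.51
(p = 0.0007) after adjusting for the baseline covariates; a smaller valve
area raises risk (HR 0.08 per cm²).  Predictions for a new patient — here
a symptomatic 79-year-old with AVA 0.61 cm² whose BNP rose from 381 to
1068 pg/ml by 1.2 years — update with each measurement:

```r
smith <- vignette_patients()$smith
h <- subject_history(smith$covariates, smith$measurements[1:3, ])
predict_event_free(fit, h, n_mc = 500, seed = 1)
#> Dynamic death-free prediction (mode mc), t = 1.20 y
#>     u    pi lower upper
#>  1.20 1.000 1.000 1.000
#>  1.81 0.811 0.291 0.973
#>  2.42 0.645 0.021 0.940
#>  2.98 0.510 0.000 0.909
#>  3.59 0.385 0.000 0.866
#>  4.20 0.287 0.000 0.823
```

Read: conditional on being alive at 1.2 years with that rising BNP
history, the point estimate of surviving to ~3 years is 0.51, with a wide
95% band reflecting both parameter and random-effect uncertainty in a
191-subject fit.  `update_prediction()` appends the next assay and renews
the curve; `dynamic_roc()` and `bootstrap_validate()` quantify how well
such scores separate patients who die within the next half-year from
those who do not:

```r
dynamic_roc(fit, cohort, t = 1, dt = 0.5)
#> Time-dependent ROC at t = 1 y, window 0.5 y: AUC = 0.738 (3 cases, 108 controls)
```

`run_full_analysis()` chains every stage (simulate → preprocess → mixed
model → two joint models → worked-example prediction panels → bootstrap
ROC) and writes CSV/JSON artifacts plus a hashed run report.  See the
methods vignette (`vignettes/dynamic-prediction-methods.Rmd`) for the
model, the numerical choices, and what the simulator does and does not
emulate.

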