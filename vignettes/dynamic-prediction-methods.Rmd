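---
title: "Joint modelling and dynamic event prediction for serial BNP in severe aortic stenosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling and dynamic event prediction for serial BNP in severe aortic stenosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with severe aortic stenosis are monitored at outpatient visits
where brain natriuretic peptide (BNP, pg/ml) is assayed repeatedly.  Two
clinical endpoints compete for attention: death and aortic-valve
intervention.  A prognosis made at diagnosis ages quickly; the clinically
natural object is a *dynamic* prediction that is revised at every visit as
new BNP values arrive.  `dynjm` implements the three-step analysis that
makes this precise:

1. a linear mixed-effects model for the evolution of log BNP;
2. joint models tying that trajectory to each time-to-event outcome;
3. subject-specific event-free probability curves that condition on
   survival so far and the accumulated measurements, validated by
   time-dependent ROC with subject-level bootstrap.

## Model

For subject $i$ with measurement times $t_{ij}$,

$$y_i(t) = x_i(t)^\top\beta + b_{0i} + b_{1i}t + \varepsilon_{ij},
\qquad b_i \sim N(0, D),\ \varepsilon_{ij}\sim N(0,\sigma^2),$$

where $y$ is natural-log BNP and $x_i(t)$ contains time (years) and the
baseline covariates: aortic valve area (AVA, cm²), age (years), symptoms
(0/1), male gender (0/1), and LV ejection fraction and serum creatinine
each divided by its sample standard deviation.  Trajectories are linear in
time: with at most four scheduled visits per subject there is no support
for more structure, and the current-value link below stays interpretable.

The survival submodel for one outcome (death *or* intervention — the two
are fitted separately, each with its own joint model) is a relative-risk
model whose hazard depends on the *current* value of the subject's
model-implied trajectory $m_i(t) = x_i(t)^\top\beta + b_{0i} + b_{1i}t$:

$$h_i(t \mid b_i) = h_0(t)\exp\{\gamma^\top w_i + \alpha\, m_i(t)\},$$

with $w_i$ the same baseline covariates and $h_0$ a Weibull baseline in
proportional-hazards form, $h_0(t) = (k/\lambda)(t/\lambda)^{k-1}$.
$\exp(\alpha)$ is the hazard ratio per unit of current log-BNP.  The
association acts on the log scale because that is the scale the
longitudinal model is specified on; this is an interpretation choice worth
flagging, since summary tables elsewhere sometimes label the same row in
pg/ml.

Both submodels share $b_i$, so the marginal likelihood integrates the
product of the longitudinal density, the survival density and the
random-effects density over $\mathbb{R}^2$ per subject.  Estimation is
full maximum likelihood over all 21 parameters — the longitudinal
parameters are *re-estimated* inside each outcome's joint fit, not frozen
at their two-stage values.

## Numerical choices

* **Quadrature.**  The 2-d integral uses tensor Gauss–Hermite quadrature
  (default 15 nodes per dimension).  By default the rule is centered at
  each subject's longitudinal posterior mode with matching curvature
  ("pseudo-adaptive").  This choice is load-bearing: with the link severed
  ($\alpha = 0$) the integrand is exactly Gaussian and the centered rule
  integrates it *exactly*, so the joint likelihood factorizes into the
  mixed-model likelihood plus a Weibull PH likelihood to machine
  precision — a property the test suite asserts at $10^{-6}$.  A
  prior-centered rule is available (`adaptive = FALSE`) but converges much
  more slowly in the number of nodes.
* **Cumulative hazard.**  Inside the likelihood, $H(t\mid b)$ uses a fixed
  Gauss–Legendre rule after the substitution $u = (s/t)^k$, which absorbs
  the $t^{k-1}$ factor exactly; the rule is exact at $\alpha = 0$ and
  accurate to ~$10^{-6}$ relative otherwise at the default 15 points.  The
  user-facing `conditional_survival()` instead integrates the hazard by
  adaptive Gauss–Kronrod (`stats::integrate`, absolute tolerance 1e-8);
  a test pins the two paths against each other.
* **Optimization.**  The mixed model profiles $\beta$ and $\sigma^2$ out
  and minimizes the 3-parameter profile deviance over the log-Cholesky
  factor of $D/\sigma^2$ (positive-definiteness by construction).  The
  joint model optimizes all 21 working parameters (log-Cholesky $D$, log
  variances, log Weibull shape/scale) by quasi-Newton iteration with
  finite-difference gradients, initialized from the two-stage fit (mixed
  model, then a Weibull PH regression on the BLUP current value at the
  observed time).  Standard errors come from the inverse numerical
  observed information at the optimum; the covariance is computed on the
  working scale, in which $\beta$, $\gamma$ and $\alpha$ are untransformed.
* **Degenerate inputs.**  A constant response drives $\hat\sigma^2$ to a
  $10^{-10}$ floor; rank-deficient designs fail fast naming the collinear
  columns; subjects with no measurements contribute a survival-only
  integral (their random-effect posterior is the prior).

## Dynamic prediction

For a new subject with covariates, measurements to time $t$, and survival
to $t$, the event-free probability at horizon $u$ is

$$\pi(u \mid t) = E\!\left[\frac{S(u \mid b)}{S(t \mid b)}
\,\middle|\, \mathcal{Y}(t), T^* > t\right].$$

Two estimators are provided:

* **Monte Carlo** (default, `n_mc = 500`): each draw samples
  $\theta^*\sim N(\hat\theta,\hat V)$ on the working scale (so variance
  and shape parameters stay admissible), then $b^*$ from
  $p(b \mid \mathcal{Y}(t), T^*>t, \theta^*)$ by independence
  Metropolis–Hastings with a multivariate-$t_4$ proposal centered at the
  empirical-Bayes mode with doubled posterior curvature, thinned 10
  steps.  The point estimate is the draw mean, the band the 2.5/97.5
  percentiles.  Curves are reproducible bitwise given the seed.
* **First-order** (deterministic): $\theta$ fixed at $\hat\theta$, the
  ratio integrated over the $b$-posterior by the same pseudo-adaptive
  Gauss–Hermite machinery.  It is the oracle the MC mode is tested
  against, and the fast path used when scoring whole cohorts for ROC.

Both satisfy $\pi(t\mid t) = 1$ exactly and are non-increasing in $u$ by
construction (each draw's ratio is a survival-ratio).  The default horizon
grid is 50 points spanning 3 years from $t$.

## Discrimination and internal validation

At landmark $t$ (default 1 year) with window $dt$ (default 0.5 years — the
approximate visit spacing), each subject still at risk is scored with
$1-\pi(t+dt\mid t)$ from their own history.  Cases are events inside
$(t, t+dt]$; controls are subjects event-free beyond $t+dt$; follow-up
ending inside the window without the outcome (censoring, or the competing
outcome) excludes the subject — the simplest defensible estimand, at the
price of ignoring within-window censoring (no inverse-probability
weighting).  AUC is the trapezoid area, identical to the Mann–Whitney
statistic with ties at 1/2.  `bootstrap_validate()` resamples whole
subjects with replacement, refits the joint model on every resample
(reduced quadrature allowed, warm-started), and reports the distribution
of apparent AUCs.  Optimism-corrected variants are out of scope.

One empirical caveat the test suite documents: apparent AUC is *not*
globally monotone in the generating association strength.  With strong
covariate effects and a late landmark, a large $\alpha$ removes high-risk
subjects before the landmark and the surviving pool is homogenized.  The
monotonicity property therefore holds — and is tested — with the
biomarker channel isolated ($\gamma = 0$, early landmark).

## The synthetic cohort

No patient-level data ship with the package; the generator produces
cohorts with the structure the analysis assumes, and its defaults *are*
the study conditions: 191 subjects; visits scheduled at 0, 0.5, 1 and 2
years with Gaussian jitter (SD 0.1 y) and a 15% missed-visit probability
(the baseline assay is never skipped); administrative censoring at 2.5
years; covariate marginals age $N(72.6, 11.4)$, 62% male, 69%
symptomatic, AVA $N(0.74, 0.27)$ truncated to (0.2, 1.0) cm² (the
severe-stenosis inclusion window), LVEF $N(61, 6.7)$%, creatinine
log-normal moment-matched to mean 89 / SD 125 µmol/L (a normal with these
moments would go negative); and the published coefficient tables as
generating truth for both submodels.  Death and intervention times are
drawn from their trajectory-linked hazards sharing the same random
effects, by inverse-transform sampling with bracketed root finding on the
cumulative hazard; the first event ends follow-up, so at most one status
is 1 — the same single-outcome simplification the analysis itself makes.

Three generating quantities are not published and were fixed once:

* the Weibull baselines, calibrated by `scripts/calibrate_truth.R` so the
  defaults reproduce ~15% deaths and ~48% interventions at $n=191$
  (frozen at shape 1.3 / scale 325 for death, shape 1.1 / scale 2.25 for
  intervention);
* the variance components $D = \begin{pmatrix}1.0 & 0.06\\ 0.06 &
  0.09\end{pmatrix}$, $\sigma^2 = 0.2$: between-subject SD of ~1 on log
  BNP (patients span orders of magnitude in pg/ml), slope SD 0.3 (a
  subject's 2-year trend can differ from the population's by roughly
  threefold on the natural scale), mild positive intercept–slope
  correlation, assay-level residual SD ~0.45;
* visit jitter and missingness, set to land near the study's ~2.9
  measurements per subject.

What the generator does **not** emulate: inter-covariate correlations
(only marginals are targeted), informative visit timing, non-linear
trajectories, and the dependence between the two outcomes beyond their
shared trajectory.  Passing tests on these cohorts show the estimators
recover the generating process they assume; they cannot show robustness
to real-data violations of that process.

## Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to keep the full suite
comfortably reproducible on a single CPU: parameter-recovery coverage uses
50 cohorts of $n=300$ at 9 quadrature nodes; bootstrap validation examples
use $B=50$ (the analysis-scale default would be $B=1000$); Monte-Carlo
oracles use $10^5$ draws per subject for likelihood checks and 4 000–10 000
draws for prediction checks.

## Known limitations

* Death and intervention are modelled marginally; the competing-risks
  structure between them is acknowledged but not modelled, so each
  model's "event-free" probability treats the other outcome as censoring.
* Only the Weibull baseline hazard is implemented.
* Only the current-value association is implemented (no slope or
  cumulative parameterizations).
* Calibration-type validation of the predictions is not provided; the
  validation here is discrimination-only.

## A worked call sequence

```{r, eval = FALSE}
library(dynjm)
cohort <- preprocess_cohort(simulate_cohort(default_truth(), 191, seed = 20))
fit <- fit_joint(cohort, "death")
hazard_ratio_table(fit)

smith <- vignette_patients()$smith
h <- subject_history(smith$covariates, smith$measurements[1:3, ])
curve <- predict_event_free(fit, h, n_mc = 500, seed = 1)
plot(curve)
update_prediction(fit, h, new_measurement = c(2, 1070), seed = 1)$curve

bootstrap_validate(cohort, "death", t = 1, dt = 0.5, B = 50, seed = 1)
```
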