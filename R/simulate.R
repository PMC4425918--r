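# Generating truth for the synthetic severe-aortic-stenosis cohort.
#
# Longitudinal fixed effects, survival coefficients and associations are
# the published point estimates used as generating values; the Weibull
# baseline-hazard parameters are never published, so they were calibrated
# once by grid search (scripts/calibrate_truth.R) to reproduce ~15% deaths
# and ~48% interventions in cohorts of 191 subjects followed <= 2.5 years,
# and then frozen here as named constants.
TRUTH_BETA <- c("(Intercept)" = 2.92, time = 0.23, ava = -1.48, age = 0.05,
                symptoms = 0.43, male = -0.34, lvef_scaled = -0.16,
                creatinine_scaled = 0.4)
TRUTH_GAMMA_DEATH <- c(ava = -2.61, age = 0.02, male = 1.12, symptoms = 1.87,
                       lvef_scaled = 0.01, creatinine_scaled = 0.18)
TRUTH_GAMMA_INTERV <- c(ava = -1.12, age = -0.04, male = 0.39,
                        symptoms = 1.08, lvef_scaled = 0.24,
                        creatinine_scaled = -1.43)
TRUTH_ALPHA_DEATH <- 0.5
TRUTH_ALPHA_INTERV <- 0.18
# unpublished variance components: chosen once as realistic for log-BNP
# (between-subject SD ~1 on the log scale, slope SD 0.3, mild positive
# intercept-slope correlation, assay residual SD ~0.45)
TRUTH_D <- matrix(c(1.0, 0.06, 0.06, 0.09), 2, 2)
TRUTH_SIGMA2 <- 0.2
# frozen calibration output (see scripts/calibrate_truth.R)
TRUTH_H0_DEATH <- list(family = "weibull", shape = 1.3, scale = 325)
TRUTH_H0_INTERV <- list(family = "weibull", shape = 1.1, scale = 2.25)

#' Default generating truth for the cohort simulator
#'
#' Returns the full generating parameter set of the simulator: joint-model
#' parameters for each outcome (shared longitudinal truth; outcome-specific
#' survival coefficients and association), marginal baseline-covariate
#' distributions matching the study population (age N(72.6, 11.4), 62%
#' male, 69% symptomatic, AVA N(0.74, 0.27) truncated to (0.2, 1.0) cm^2,
#' LVEF N(61, 6.7)%, creatinine log-normal moment-matched to mean 89 /
#' SD 125 micromol/L), the scheduled visit grid (baseline, 6, 12 and 24
#' months) with jitter and missed visits, and administrative censoring at
#' 2.5 years.
#'
#' @return object of class `jm_truth`.
#' @export
default_truth <- function() {
  cv <- 125 / 89
  sdlog <- sqrt(log(1 + cv^2))
  truth <- list(
    params_death = joint_parameters(TRUTH_BETA, TRUTH_D, TRUTH_SIGMA2,
                                    TRUTH_GAMMA_DEATH, TRUTH_ALPHA_DEATH,
                                    TRUTH_H0_DEATH),
    params_intervention = joint_parameters(TRUTH_BETA, TRUTH_D, TRUTH_SIGMA2,
                                           TRUTH_GAMMA_INTERV,
                                           TRUTH_ALPHA_INTERV,
                                           TRUTH_H0_INTERV),
    covariate_model = list(
      age = list(dist = "normal", mean = 72.6, sd = 11.4),
      male = list(dist = "bernoulli", p = 0.62),
      symptoms = list(dist = "bernoulli", p = 0.69),
      ava = list(dist = "truncnormal", mean = 0.74, sd = 0.27,
                 lower = 0.2, upper = 1.0),
      lvef = list(dist = "normal", mean = 61, sd = 6.7),
      creatinine = list(dist = "lognormal",
                        meanlog = log(89) - sdlog^2 / 2, sdlog = sdlog)),
    scaling = c(lvef = 6.7, creatinine = 125),
    visit_schedule = c(0, 0.5, 1, 2),
    visit_jitter_sd = 0.1,
    p_missed_visit = 0.15,
    admin_censor = 2.5)
  structure(truth, class = "jm_truth")
}

validate_truth <- function(truth) {
  stopifnot(inherits(truth, "jm_truth"))
  if (truth$p_missed_visit < 0 || truth$p_missed_visit > 1)
    dynjm_error("p_missed_visit must be in [0,1]", "dynjm_domain_error")
  if (truth$admin_censor <= max(truth$visit_schedule))
    dynjm_error("admin_censor must exceed the last scheduled visit",
                "dynjm_domain_error")
  if (truth$visit_jitter_sd < 0 || any(truth$scaling <= 0))
    dynjm_error("scale parameters must be positive", "dynjm_domain_error")
  invisible(truth)
}

draw_covariates <- function(cm, n) {
  rtrunc <- function(n, m, s, lo, hi) {
    u <- runif(n, pnorm((lo - m) / s), pnorm((hi - m) / s))
    m + s * qnorm(u)
  }
  data.frame(
    age = rnorm(n, cm$age$mean, cm$age$sd),
    male = rbinom(n, 1, cm$male$p),
    symptoms = rbinom(n, 1, cm$symptoms$p),
    ava = rtrunc(n, cm$ava$mean, cm$ava$sd, cm$ava$lower, cm$ava$upper),
    lvef = rnorm(n, cm$lvef$mean, cm$lvef$sd),
    creatinine = exp(rnorm(n, cm$creatinine$meanlog, cm$creatinine$sdlog)))
}

# invert H(T | b) = E on (0, admin] by bracketed root finding; the
# cumulative hazard uses the same Gauss-Legendre rule as the likelihood
invert_cum_hazard <- function(E, alpha, shape, scale, eta, c0, c1, admin,
                              gl) {
  Hfun <- function(t)
    cum_hazard_draws(alpha, shape, scale, eta, c0, c1,
                     matrix(0, 1, 2), t, gl)
  Hadm <- Hfun(admin)
  if (!is.finite(Hadm))
    dynjm_error("cumulative hazard not finite at admin censoring",
                "dynjm_numerical_error")
  if (Hadm < E) return(c(time = admin, status = 0))
  root <- uniroot(function(t) Hfun(t) - E, lower = 1e-8, upper = admin,
                  tol = 1e-10)
  c(time = root$root, status = 1)
}

#' Simulate one event time by inverse-transform sampling
#'
#' Draws U ~ Uniform(0,1) and solves \eqn{H(T \mid b) = -\log U} for T by
#' bracketed root finding on the cumulative hazard of the joint model;
#' administrative censoring applies at `admin_censor`.
#'
#' @param params a [joint_parameters()] object.
#' @param covariates named raw-scale baseline covariates.
#' @param b length-2 random-effect value.
#' @param scaling_constants named SDs used to scale lvef/creatinine.
#' @param admin_censor administrative censoring time in years.
#' @param seed optional integer seed.
#' @return named vector `c(time, status)`; status 1 if the root precedes
#'   censoring.
#' @export
simulate_event_time <- function(params, covariates, b, scaling_constants,
                                admin_censor = 2.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x0 <- subject_x0(covariates, scaling_constants)
  w <- x0[1, c("ava", "age", "male", "symptoms", "lvef_scaled",
               "creatinine_scaled")]
  invert_cum_hazard(-log(runif(1)), params$alpha, params$h0$shape,
                    params$h0$scale, sum(params$gamma * w),
                    sum(x0[1, ] * params$beta) + b[1],
                    params$beta[[TIME_COL]] + b[2], admin_censor, gl_unit())
}

#' Simulate a linked longitudinal-survival cohort
#'
#' Per subject: baseline covariates are drawn from the truth's marginal
#' distributions, a random intercept/slope pair from N(0, D), then a death
#' time and an intervention time are drawn from their respective
#' trajectory-linked hazards (sharing the same random effects).  Follow-up
#' ends at the first of the two events or administrative censoring, so at
#' most one status is 1.  The biomarker is measured at jittered scheduled
#' visits that precede the end of follow-up (the baseline visit is never
#' skipped; later visits are missed independently with probability
#' `p_missed_visit`), with value = exp(trajectory + residual) in pg/ml.
#'
#' @param truth a [default_truth()]-style `jm_truth`.
#' @param n number of subjects (>= 2).
#' @param seed integer seed; the cohort is fully reproducible given
#'   (truth, n, seed).
#' @return an unpreprocessed `jm_cohort`; the attribute
#'   `n_without_measurements` counts subjects whose follow-up ended before
#'   their first jittered visit.
#' @export
simulate_cohort <- function(truth, n, seed) {
  validate_truth(truth)
  if (n < 2) dynjm_error("n must be >= 2", "dynjm_domain_error")
  set.seed(seed)
  gl <- gl_unit()
  cov <- draw_covariates(truth$covariate_model, n)
  cov$lvef_scaled <- cov$lvef / truth$scaling[["lvef"]]
  cov$creatinine_scaled <- cov$creatinine / truth$scaling[["creatinine"]]
  pd <- truth$params_death; pi_ <- truth$params_intervention
  Lb <- t(chol(pd$D))
  B <- t(Lb %*% matrix(rnorm(2 * n), 2, n))
  x0 <- baseline_design(cov)
  c0 <- as.numeric(x0 %*% pd$beta) + B[, 1]
  c1 <- pd$beta[[TIME_COL]] + B[, 2]
  W <- cbind(cov$ava, cov$age, cov$male, cov$symptoms, cov$lvef_scaled,
             cov$creatinine_scaled)
  eta_d <- as.numeric(W %*% pd$gamma)
  eta_i <- as.numeric(W %*% pi_$gamma)
  Ed <- -log(runif(n)); Ei <- -log(runif(n))

  obs_time <- numeric(n); status_d <- integer(n); status_i <- integer(n)
  for (i in seq_len(n)) {
    dth <- invert_cum_hazard(Ed[i], pd$alpha, pd$h0$shape, pd$h0$scale,
                             eta_d[i], c0[i], c1[i], truth$admin_censor, gl)
    itv <- invert_cum_hazard(Ei[i], pi_$alpha, pi_$h0$shape, pi_$h0$scale,
                             eta_i[i], c0[i], c1[i], truth$admin_censor, gl)
    if (dth["status"] == 1 && dth["time"] <= itv["time"]) {
      obs_time[i] <- dth["time"]; status_d[i] <- 1L
    } else if (itv["status"] == 1) {
      obs_time[i] <- itv["time"]; status_i[i] <- 1L
    } else {
      obs_time[i] <- truth$admin_censor
    }
  }

  sched <- truth$visit_schedule
  long <- vector("list", n)
  for (i in seq_len(n)) {
    tv <- pmax(sched + rnorm(length(sched), 0, truth$visit_jitter_sd), 0)
    keep <- c(TRUE, runif(length(sched) - 1) > truth$p_missed_visit)
    tv <- sort(tv[keep])
    tv <- tv[tv <= obs_time[i]]
    if (!length(tv)) next
    val <- exp(c0[i] + c1[i] * tv +
                 rnorm(length(tv), 0, sqrt(pd$sigma2)))
    long[[i]] <- data.frame(subject_id = sprintf("S%04d", i), time = tv,
                            value = val)
  }
  empty <- sum(vapply(long, is.null, logical(1)))
  long <- do.call(rbind, long[!vapply(long, is.null, logical(1))])
  surv <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                     obs_time = obs_time, status_death = status_d,
                     status_intervention = status_i, ava = cov$ava,
                     age = cov$age, symptoms = cov$symptoms,
                     male = cov$male, lvef = cov$lvef,
                     creatinine = cov$creatinine)
  out <- new_cohort(long, surv)
  attr(out, "n_without_measurements") <- empty
  out
}

#' Write / read a generating-truth file
#'
#' Flat YAML mirroring the `jm_truth` structure, so simulator settings can
#' be stored beside generated data.
#'
#' @param truth a `jm_truth`.
#' @param path file path.
#' @return `write_truth` invisibly returns `path`; `read_truth` a
#'   `jm_truth`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    beta = as.list(truth$params_death$beta),
    D = as.numeric(truth$params_death$D), sigma2 = truth$params_death$sigma2,
    gamma_death = as.list(truth$params_death$gamma),
    alpha_death = truth$params_death$alpha,
    h0_death = truth$params_death$h0[-1],
    gamma_intervention = as.list(truth$params_intervention$gamma),
    alpha_intervention = truth$params_intervention$alpha,
    h0_intervention = truth$params_intervention$h0[-1],
    covariate_model = truth$covariate_model,
    scaling = as.list(truth$scaling),
    visit_schedule = truth$visit_schedule,
    visit_jitter_sd = truth$visit_jitter_sd,
    p_missed_visit = truth$p_missed_visit,
    admin_censor = truth$admin_censor)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  o <- yaml::read_yaml(path)
  mk <- function(gam, alp, h0)
    joint_parameters(unlist(o$beta), matrix(o$D, 2, 2), o$sigma2,
                     unlist(gam), alp,
                     c(list(family = "weibull"), h0))
  structure(list(
    params_death = mk(o$gamma_death, o$alpha_death, o$h0_death),
    params_intervention = mk(o$gamma_intervention, o$alpha_intervention,
                             o$h0_intervention),
    covariate_model = o$covariate_model,
    scaling = unlist(o$scaling),
    visit_schedule = as.numeric(o$visit_schedule),
    visit_jitter_sd = o$visit_jitter_sd,
    p_missed_visit = o$p_missed_visit,
    admin_censor = o$admin_censor), class = "jm_truth")
}
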