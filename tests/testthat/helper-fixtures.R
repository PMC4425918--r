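# Shared fixtures, memoized so expensive fits are computed once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures))
    assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# hand-built 2-subject tables (3 visits each)
toy_tables <- function() {
  long <- data.frame(
    subject_id = rep(c("A", "B"), each = 3),
    time = c(0, 0.5, 1, 0, 0.6, 1.2),
    value = c(64, 70, 78, 381, 287, 1068))
  surv <- data.frame(
    subject_id = c("A", "B"), obs_time = c(2, 1.5),
    status_death = c(0, 1), status_intervention = c(0, 0),
    ava = c(0.96, 0.61), age = c(72, 79), symptoms = c(0, 1),
    male = c(1, 1), lvef = c(61, 55), creatinine = c(92, 130))
  list(long = long, surv = surv)
}

toy_cohort <- function() {
  tt <- toy_tables()
  new_cohort(tt$long, tt$surv)
}

sim_cohort <- function(n, seed) {
  memo(sprintf("cohort_%d_%d", n, seed),
       preprocess_cohort(simulate_cohort(default_truth(), n, seed)))
}

# standard mid-size fitted joint model (death), shared across test files
fit_std <- function() {
  memo("fit_std",
       fit_joint(sim_cohort(120, 3), "death", config = list(nodes = 9)))
}

# a jm_fit-shaped object carrying the generating truth, for fast scoring
# without estimation noise
truth_fit <- function(outcome = "death", truth = default_truth()) {
  params <- if (outcome == "death") truth$params_death else
    truth$params_intervention
  structure(list(params = params, theta = dynjm:::params_to_theta(params),
                 vcov = NULL, loglik = NA_real_, outcome = outcome,
                 quadrature = 15L, adaptive = TRUE, gl_points = 15L,
                 converged = TRUE, scaling_constants = truth$scaling),
            class = "jm_fit")
}

# independent Weibull proportional-hazards log-likelihood (closed form)
weibull_ph_loglik <- function(Tobs, delta, eta, shape, scale) {
  sum(delta * (log(shape / scale) + (shape - 1) * log(Tobs / scale) + eta) -
        (Tobs / scale)^shape * exp(eta))
}

# brute-force Monte-Carlo evaluation of one subject's joint likelihood
# contribution (prior draws of b), with a delta-method standard error of
# the log; independent of the quadrature code path
mc_subject_loglik <- function(params, cohort, outcome, subject, M,
                              gl_points = 15) {
  dd <- dynjm:::long_design(cohort)
  sv <- dynjm:::surv_design(cohort$survival, outcome)
  gl <- dynjm:::gl_unit(gl_points)
  i <- subject
  Lb <- t(chol(params$D))
  B <- t(Lb %*% matrix(rnorm(2 * M), 2))
  ll <- numeric(M)
  rows <- seq.int(dd$sidx[i] + 1, length.out = dd$sidx[i + 1] - dd$sidx[i])
  if (length(rows)) {
    R <- matrix(dd$y[rows] - dd$X[rows, , drop = FALSE] %*% params$beta,
                M, length(rows), byrow = TRUE) -
      B %*% t(dd$Z[rows, , drop = FALSE])
    ll <- -0.5 * length(rows) * log(2 * pi * params$sigma2) -
      rowSums(R^2) / (2 * params$sigma2)
  }
  k <- params$h0$shape; lam <- params$h0$scale
  eta <- sum(sv$W[i, ] * params$gamma)
  c0 <- sum(dd$x0[i, ] * params$beta) + B[, 1]
  c1 <- params$beta[[2]] + B[, 2]
  H <- dynjm:::cum_hazard_draws(params$alpha, k, lam, eta, c0, c1,
                                matrix(0, M, 2), sv$Tobs[i], gl)
  ls <- -H
  if (sv$delta[i] == 1)
    ls <- ls + log(k / lam) + (k - 1) * log(sv$Tobs[i] / lam) + eta +
      params$alpha * (c0 + c1 * sv$Tobs[i])
  lw <- ll + ls
  m <- max(lw)
  w <- exp(lw - m)
  list(loglik = m + log(mean(w)), se = sd(w) / (sqrt(M) * mean(w)))
}
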