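# balanced no-random-effect data for the closed-form GLS checks
gls_fixture <- function(n = 50, sigma = 0.5, seed = 99) {
  set.seed(seed)
  times <- c(0, 0.5, 1, 2)
  surv <- data.frame(
    subject_id = sprintf("P%03d", seq_len(n)), obs_time = 3,
    status_death = 0, status_intervention = 0,
    ava = runif(n, 0.3, 1), age = rnorm(n, 72, 10),
    symptoms = rbinom(n, 1, 0.6), male = rbinom(n, 1, 0.5),
    lvef = rnorm(n, 61, 7), creatinine = rlnorm(n, 4.4, 0.5))
  long <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(subject_id = surv$subject_id[i], time = times, value = 1)))
  co <- preprocess_cohort(new_cohort(long, surv))
  dd <- dynjm:::long_design(co)
  beta <- c(3, 0.2, -1.5, 0.05, 0.4, -0.3, -0.15, 0.4)
  co$longitudinal$value_log <-
    as.numeric(dd$X %*% beta) + rnorm(nrow(dd$X), 0, sigma)
  list(cohort = co, X = dd$X, Z = dd$Z, beta = beta)
}

# direct stacked-design GLS at a given marginal covariance (block diagonal
# with identical 4x4 blocks here)
gls_direct <- function(X, y, Vblock) {
  n <- nrow(X) / nrow(Vblock)
  Vi <- solve(Vblock)
  XtVX <- 0; XtVy <- 0
  for (i in seq_len(n)) {
    r <- ((i - 1) * nrow(Vblock) + 1):(i * nrow(Vblock))
    XtVX <- XtVX + crossprod(X[r, ], Vi %*% X[r, ])
    XtVy <- XtVy + crossprod(X[r, ], Vi %*% y[r])
  }
  as.numeric(solve(XtVX, XtVy))
}

test_that("ML fixed effects equal the stacked-design GLS closed form", {
  fx <- gls_fixture()
  fit <- fit_lmm(fx$cohort)
  y <- fx$cohort$longitudinal$value_log
  Zb <- cbind(1, c(0, 0.5, 1, 2))
  # GLS at the fitted marginal covariance: independent of the profiled path
  Vhat <- Zb %*% fit$D %*% t(Zb) + fit$sigma2 * diag(4)
  expect_equal(unname(fit$beta), gls_direct(fx$X, y, Vhat),
               tolerance = 1e-8)
  # data were generated with D = 0, so the fit is close to plain OLS
  ols <- gls_direct(fx$X, y, diag(4))
  expect_lt(max(abs(fit$beta - ols)), 0.05)
})

test_that("profiled beta matches GLS at known D (profile equivalence)", {
  fx <- gls_fixture(seed = 123)
  dd <- dynjm:::long_design(fx$cohort)
  blocks <- dynjm:::lmm_blocks(dd)
  psi <- c(log(0.7), 0, log(0.4))   # fixed, known Dstar (diagonal-ish)
  out <- dynjm:::lmm_profile_dev(psi, blocks, details = TRUE)
  L <- matrix(c(exp(psi[1]), psi[2], 0, exp(psi[3])), 2, 2)
  Zb <- cbind(1, c(0, 0.5, 1, 2))
  V <- Zb %*% (L %*% t(L)) %*% t(Zb) + diag(4)
  expect_equal(out$beta,
               gls_direct(fx$X, fx$cohort$longitudinal$value_log, V),
               tolerance = 1e-8)
})

test_that("fixed effects recover generating values within 3 SEs (n=300)", {
  co <- sim_cohort(300, 17)
  fit <- fit_lmm(co)
  truth <- c(2.92, 0.23, -1.48, 0.05, 0.43, -0.34, -0.16, 0.4)
  est <- fit$beta; se <- fit$se_beta
  # scaled-covariate coefficients are compared per raw unit: the scaled
  # column's estimand depends on the replicate's sample SD
  gen_sd <- default_truth()$scaling
  for (j in 7:8) {
    s <- co$scaling_constants[[c("lvef", "creatinine")[j - 6]]]
    est[j] <- est[j] / s; se[j] <- se[j] / s
    truth[j] <- truth[j] / gen_sd[[c("lvef", "creatinine")[j - 6]]]
  }
  expect_true(all(abs(est - truth) < 3 * se))
  # BLUPs average to ~0 over subjects
  expect_lt(max(abs(colMeans(fit$blups))),
            1e-1 * max(apply(fit$blups, 2, sd)))
})

test_that("fit agrees with an independent ML mixed-model implementation", {
  co <- sim_cohort(120, 3)
  fit <- fit_lmm(co)
  d <- merge(co$longitudinal, co$survival, by = "subject_id")
  ml <- nlme::lme(value_log ~ time + ava + age + symptoms + male +
                    lvef_scaled + creatinine_scaled,
                  random = ~ time | subject_id, data = d, method = "ML",
                  control = nlme::lmeControl(opt = "optim"))
  expect_equal(unname(fit$beta), unname(nlme::fixef(ml)), tolerance = 0.02)
  # both maximize the same ML criterion; ours must not be worse
  expect_gte(fit$loglik, as.numeric(logLik(ml)) - 1e-3)
  expect_lt(abs(fit$loglik - as.numeric(logLik(ml))), 0.1)
})

test_that("fitted parameters are a local maximum of the marginal likelihood", {
  co <- sim_cohort(120, 3)
  fit <- fit_lmm(co)
  ll0 <- lmm_marginal_loglik(co, fit$beta, fit$D, fit$sigma2)
  expect_equal(ll0, fit$loglik, tolerance = 1e-8)
  set.seed(1)
  for (k in 1:25) {
    beta_p <- fit$beta * (1 + rnorm(8, 0, 0.02))
    L <- t(chol(fit$D)) * exp(rnorm(1, 0, 0.05))
    s2 <- fit$sigma2 * exp(rnorm(1, 0, 0.05))
    expect_lt(lmm_marginal_loglik(co, beta_p, L %*% t(L), s2), ll0)
  }
})

test_that("constant response degenerates to intercept-only with floor variance", {
  fx <- gls_fixture(n = 20, seed = 7)
  co <- fx$cohort
  co$longitudinal$value <- exp(2.5)
  co$longitudinal$value_log <- 2.5
  fit <- fit_lmm(co)
  expect_equal(unname(fit$beta[1]), 2.5, tolerance = 1e-6)
  expect_lt(max(abs(fit$beta[-1])), 1e-6)
  expect_lte(fit$sigma2, 1e-8)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  tt <- toy_tables()
  tt$surv$age <- tt$surv$lvef          # collinear after scaling (2 subjects)
  co <- preprocess_cohort(new_cohort(tt$long, tt$surv))
  expect_error(fit_lmm(co), class = "dynjm_singular_design_error")
})

test_that("trajectory prediction: population mean, covariate offsets, shrinkage", {
  fit <- truth_fit()   # well-conditioned D, so the shrinkage limit is clean
  lmm <- structure(list(beta = fit$params$beta, D = fit$params$D,
                        sigma2 = fit$params$sigma2,
                        scaling_constants = fit$scaling_constants),
                   class = "jm_lmm")
  cov1 <- list(ava = 0.96, age = 72, symptoms = 0, male = 1, lvef = 61,
               creatinine = 92)
  times <- seq(0, 2, by = 0.25)
  # no measurements -> x(t)'beta exactly
  x0 <- dynjm:::subject_x0(cov1, fit$scaling_constants)
  pop <- vapply(times, function(t) {
    x <- x0; x[1, 2] <- t; sum(x * lmm$beta)
  }, numeric(1))
  expect_equal(predict_trajectory(lmm, cov1, NULL, times), pop)
  # two subjects differing only in AVA: constant vertical offset a*beta_ava
  cov2 <- cov1; cov2$ava <- 0.61
  d <- predict_trajectory(lmm, cov1, NULL, times) -
    predict_trajectory(lmm, cov2, NULL, times)
  expect_equal(d, rep((0.96 - 0.61) * lmm$beta[["ava"]], length(times)))
  # dense noiseless measurements + tiny sigma2: prediction -> observation
  lmm2 <- lmm; lmm2$sigma2 <- 1e-8
  tm <- seq(0, 2, by = 0.1)
  truem <- pop[1] + 0.8 - 0.3 * tm + (lmm$beta[["time"]]) * tm
  ms <- data.frame(time = tm, value = exp(truem))
  pr <- predict_trajectory(lmm2, cov1, ms, tm)
  expect_equal(pr, truem, tolerance = 1e-4)
  expect_error(predict_trajectory(lmm, cov1, NULL, -1),
               class = "dynjm_domain_error")
})
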