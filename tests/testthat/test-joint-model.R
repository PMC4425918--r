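test_that("severed link (alpha = 0) factorizes into LMM + Weibull PH likelihoods", {
  co <- sim_cohort(20, 7)
  p0 <- default_truth()$params_death
  p0$alpha <- 0
  jl <- joint_loglik(p0, co, "death", nodes = 15)
  lm <- lmm_marginal_loglik(co, p0$beta, p0$D, p0$sigma2)
  sv <- dynjm:::surv_design(co$survival, "death")
  ph <- weibull_ph_loglik(sv$Tobs, sv$delta,
                          as.numeric(sv$W %*% p0$gamma),
                          p0$h0$shape, p0$h0$scale)
  expect_equal(jl, lm + ph, tolerance = 1e-6)
})

test_that("quadrature agrees with brute-force Monte-Carlo integration", {
  co <- sim_cohort(20, 7)
  p <- default_truth()$params_death
  lls <- joint_loglik(p, co, "death", nodes = 25, per_subject = TRUE)
  set.seed(42)
  mc <- vapply(1:20, function(i)
    unlist(mc_subject_loglik(p, co, "death", i, M = 30000)), numeric(2))
  z_total <- (sum(lls) - sum(mc[1, ])) / sqrt(sum(mc[2, ]^2))
  expect_lt(abs(z_total), 3)
})

test_that("a subject with no measurements contributes the survival-only integral", {
  tt <- toy_tables()
  tt$long <- tt$long[tt$long$subject_id == "A", ]   # B: survival only
  co <- preprocess_cohort(new_cohort(tt$long, tt$surv),
                          constants = c(lvef = 6.7, creatinine = 125))
  p <- default_truth()$params_death
  lls <- joint_loglik(p, co, "death", nodes = 25, per_subject = TRUE)
  # independent dense-grid integration of int p(T, delta | b) p(b) db
  sv <- dynjm:::surv_design(co$survival, "death")
  dd <- dynjm:::long_design(co)
  gl <- dynjm:::gl_unit()
  gr <- seq(-6, 6, length.out = 201)
  bg <- as.matrix(expand.grid(b1 = gr, b2 = gr))
  L <- t(chol(p$D))
  B <- bg %*% t(L)   # b = L z; integrate over standard-normal z
  i <- 2
  eta <- sum(sv$W[i, ] * p$gamma)
  c0 <- sum(dd$x0[i, ] * p$beta) + B[, 1]
  c1 <- p$beta[[2]] + B[, 2]
  H <- dynjm:::cum_hazard_draws(p$alpha, p$h0$shape, p$h0$scale, eta, c0,
                                c1, matrix(0, nrow(B), 2), sv$Tobs[i], gl)
  k <- p$h0$shape; lam <- p$h0$scale
  f <- exp(-H + sv$delta[i] * (log(k / lam) +
                                 (k - 1) * log(sv$Tobs[i] / lam) + eta +
                                 p$alpha * (c0 + c1 * sv$Tobs[i])))
  # integrate over standard-normal z with the grid spacing
  dz <- diff(gr)[1]
  val <- sum(f * exp(-0.5 * rowSums(bg^2)) / (2 * pi)) * dz^2
  expect_equal(lls[2], log(val), tolerance = 1e-4)
})

test_that("joint fit recovers generating parameters and beats its initializer", {
  co <- sim_cohort(300, 17)
  fit <- fit_joint(co, "death",
                   config = list(nodes = 9, gl_points = 8, grad = "forward",
                                 rel_tol = 1e-9))
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_init)
  tr <- default_truth()
  se <- sqrt(diag(fit$vcov))
  est <- c(fit$params$beta, fit$params$gamma, fit$params$alpha)
  tru <- c(tr$params_death$beta, tr$params_death$gamma,
           tr$params_death$alpha)
  ses <- se[c(dynjm:::PAR_IDX$beta, dynjm:::PAR_IDX$gamma,
              dynjm:::PAR_IDX$alpha)]
  # scaled covariates compared per raw unit (see test-lmm.R)
  gen_sd <- tr$scaling; fit_sd <- co$scaling_constants
  resc <- function(v, idx_l, idx_c) {
    v[idx_l] <- v[idx_l] / fit_sd[["lvef"]]
    v[idx_c] <- v[idx_c] / fit_sd[["creatinine"]]; v
  }
  est <- resc(est, c(7, 13), c(8, 14)); ses <- resc(ses, c(7, 13), c(8, 14))
  tru[c(7, 13)] <- tru[c(7, 13)] / gen_sd[["lvef"]]
  tru[c(8, 14)] <- tru[c(8, 14)] / gen_sd[["creatinine"]]
  expect_true(all(abs(est - tru) < 3 * ses))
})

test_that("null-association data give |z_alpha| < 3 and LMM-consistent betas", {
  tr <- default_truth()
  tr$params_death$alpha <- 0
  tr$params_intervention$alpha <- 0
  co <- preprocess_cohort(simulate_cohort(tr, 200, 23))
  fit <- fit_joint(co, "death",
                   config = list(nodes = 9, gl_points = 8, grad = "forward"))
  se_alpha <- sqrt(diag(fit$vcov))[dynjm:::PAR_IDX$alpha]
  expect_lt(abs(fit$params$alpha / se_alpha), 3)
  lmm <- fit_lmm(co)
  expect_true(all(abs(fit$params$beta - lmm$beta) < 2 * lmm$se_beta))
})

test_that("estimates are stable under quadrature refinement (9 vs 15 nodes)", {
  co <- sim_cohort(120, 3)
  f9 <- fit_joint(co, "death", config = list(nodes = 9, hessian = FALSE))
  f15 <- fit_joint(co, "death", config = list(nodes = 15, hessian = FALSE,
                                              init = f9$params))
  expect_lt(max(abs(f9$theta - f15$theta)), 0.01)
  # loglik quadrature convergence at the optimum
  ll15 <- joint_loglik(f15$params, co, "death", nodes = 15)
  ll21 <- joint_loglik(f15$params, co, "death", nodes = 21)
  expect_lt(abs(ll21 - ll15) / abs(ll15), 1e-5)
  # prior-centered (non-adaptive) rule converges to the same integral,
  # but needs far more nodes than the posterior-centered default
  ll_std21 <- joint_loglik(f15$params, co, "death", nodes = 21,
                           adaptive = FALSE)
  ll_std41 <- joint_loglik(f15$params, co, "death", nodes = 41,
                           adaptive = FALSE)
  expect_lt(abs(ll_std41 - ll21) / abs(ll21), 2e-4)
  expect_lt(abs(ll_std41 - ll21), abs(ll_std21 - ll21))
})

test_that("hazard-ratio table reproduces exp(coef) and Wald p-values", {
  tr <- default_truth()
  tab <- hazard_ratio_table(tr$params_death)
  expect_equal(tab$HR[tab$term == "symptoms"], 6.49)     # coef 1.87
  expect_equal(tab$HR[tab$term == "ava"], 0.07)          # coef -2.61
  p0 <- tr$params_death; p0$gamma["age"] <- 0
  expect_equal(hazard_ratio_table(p0)$HR[3], 1)          # exp(0) = 1
  fit <- fit_std()
  tab <- hazard_ratio_table(fit)
  expect_equal(tab$HR, round(exp(tab$coef), 2))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})

test_that("conditional survival matches the severed-link closed form and is monotone", {
  tr <- default_truth()
  p <- tr$params_death
  cov <- list(ava = 0.8, age = 70, symptoms = 1, male = 1, lvef = 60,
              creatinine = 95)
  sc <- tr$scaling
  expect_equal(conditional_survival(p, cov, c(0.3, -0.1), 0, sc), 1)
  expect_error(conditional_survival(p, cov, c(0, 0), -0.5, sc),
               class = "dynjm_domain_error")
  # alpha = 0: S(t) = exp(-(t/scale)^shape * exp(gamma'w)) exactly
  p0 <- p; p0$alpha <- 0
  x0 <- dynjm:::subject_x0(cov, sc)
  eta <- sum(p0$gamma * x0[1, c("ava", "age", "male", "symptoms",
                                "lvef_scaled", "creatinine_scaled")])
  ts <- c(0.5, 1, 2, 2.5)
  expect_equal(conditional_survival(p0, cov, c(1, 1), ts, sc),
               exp(-(ts / p0$h0$scale)^p0$h0$shape * exp(eta)),
               tolerance = 1e-8)
  # monotone non-increasing on a dense grid, for nonzero association too
  s <- conditional_survival(p, cov, c(0.5, 0.2), seq(0, 3, length.out = 100),
                            sc)
  expect_true(all(diff(s) <= 0) && all(s >= 0 & s <= 1))
  # the Gauss-Legendre path used in the likelihood matches the adaptive one
  si <- dynjm:::subject_surv_inputs(p, x0)
  Hgl <- dynjm:::cum_hazard_draws(p$alpha, p$h0$shape, p$h0$scale, si$eta,
                                  si$c0 + 0.5, si$c1 + 0.2,
                                  matrix(0, 1, 2), 2.0, dynjm:::gl_unit())
  expect_equal(exp(-Hgl), conditional_survival(p, cov, c(0.5, 0.2), 2, sc),
               tolerance = 1e-6)
})

test_that("fits serialize to text and restore identically", {
  fit <- fit_std()
  path <- tempfile(fileext = ".json")
  write_joint_fit(fit, path)
  fit2 <- read_joint_fit(path)
  expect_equal(fit2$theta, fit$theta)
  expect_equal(fit2$vcov, fit$vcov, ignore_attr = TRUE)
  expect_equal(fit2$params$alpha, fit$params$alpha)
  expect_identical(fit2$outcome, fit$outcome)
  # restored fits predict identically
  h <- subject_history(vignette_patients()$jones$covariates,
                       vignette_patients()$jones$measurements)
  c1 <- predict_event_free(fit, h, u_grid = c(2, 3), mode = "first_order")
  c2 <- predict_event_free(fit2, h, u_grid = c(2, 3), mode = "first_order")
  expect_equal(c1$pi, c2$pi, tolerance = 1e-12)
})

test_that("degenerate outcomes and invalid parameters are rejected", {
  tt <- toy_tables()
  tt$surv$status_death <- c(0, 0)
  co <- preprocess_cohort(new_cohort(tt$long, tt$surv),
                          constants = c(lvef = 6.7, creatinine = 125))
  expect_error(fit_joint(co, "death"),
               class = "dynjm_degenerate_outcome_error")
  p <- default_truth()$params_death
  expect_error(joint_parameters(p$beta, matrix(c(1, 2, 2, 1), 2), p$sigma2,
                                p$gamma, p$alpha, p$h0),
               class = "dynjm_domain_error")
  expect_error(joint_parameters(p$beta, p$D, -1, p$gamma, p$alpha, p$h0),
               class = "dynjm_domain_error")
  expect_error(joint_parameters(p$beta, p$D, p$sigma2, p$gamma, p$alpha,
                                list(family = "weibull", shape = -1,
                                     scale = 2)),
               class = "dynjm_domain_error")
})
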