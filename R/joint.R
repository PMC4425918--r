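# working-parameter layout for one outcome's joint model (21 parameters)
PAR_IDX <- list(beta = 1:8, chol = 9:11, lsig = 12L, gamma = 13:18,
                alpha = 19L, lshape = 20L, lscale = 21L)

#' Bundle the full parameter set of one outcome's joint model
#'
#' @param beta longitudinal fixed effects, length 8 (see [fit_lmm()]).
#' @param D 2x2 symmetric positive-definite random-effects covariance.
#' @param sigma2 residual variance (> 0).
#' @param gamma baseline-covariate log-hazard coefficients, length 6
#'   (ava, age, male, symptoms, lvef_scaled, creatinine_scaled).
#' @param alpha association coefficient: log hazard ratio per unit of the
#'   current log-biomarker value \eqn{m_i(t)}.
#' @param h0 baseline hazard: `list(family = "weibull", shape, scale)`,
#'   proportional-hazards parameterization
#'   \eqn{h_0(t) = (k/\lambda)(t/\lambda)^{k-1}}.
#' @return object of class `jm_parameters`.
#' @export
joint_parameters <- function(beta, D, sigma2, gamma, alpha, h0) {
  stopifnot(length(beta) == 8, length(gamma) == 6, length(alpha) == 1)
  D <- unname(as.matrix(D))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) ||
      any(eigen(D, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    dynjm_error("D must be symmetric positive semi-definite",
                "dynjm_domain_error")
  if (sigma2 <= 0)
    dynjm_error("sigma2 must be > 0", "dynjm_domain_error")
  if (!identical(h0$family, "weibull") || h0$shape <= 0 || h0$scale <= 0)
    dynjm_error("h0 must be list(family='weibull', shape>0, scale>0)",
                "dynjm_domain_error")
  structure(list(beta = setNames(as.numeric(beta), LMM_TERMS), D = D,
                 sigma2 = sigma2,
                 gamma = setNames(as.numeric(gamma), SURV_TERMS),
                 alpha = as.numeric(alpha), h0 = h0),
            class = "jm_parameters")
}

theta_to_params <- function(theta) {
  L <- matrix(c(exp(theta[9]), theta[10], 0, exp(theta[11])), 2, 2)
  joint_parameters(beta = theta[PAR_IDX$beta], D = L %*% t(L),
                   sigma2 = exp(theta[PAR_IDX$lsig]),
                   gamma = theta[PAR_IDX$gamma],
                   alpha = theta[PAR_IDX$alpha],
                   h0 = list(family = "weibull",
                             shape = exp(theta[PAR_IDX$lshape]),
                             scale = exp(theta[PAR_IDX$lscale])))
}

params_to_theta <- function(params) {
  L <- t(chol(params$D + diag(1e-10, 2)))
  unname(c(params$beta, log(L[1, 1]), L[2, 1], log(L[2, 2]),
           log(params$sigma2), params$gamma, params$alpha,
           log(params$h0$shape), log(params$h0$scale)))
}

theta_names <- function() {
  c(LMM_TERMS, "log_chol_D11", "chol_D21", "log_chol_D22", "log_sigma2",
    paste0("gamma_", SURV_TERMS), "alpha", "log_shape", "log_scale")
}

#' Joint log-likelihood of longitudinal and survival data
#'
#' Evaluates \eqn{\sum_i \log \int p(y_i \mid b)\, p(T_i, \delta_i \mid b)
#' \, p(b)\, db} for the shared-random-effects joint model whose hazard is
#' \eqn{h_i(t \mid b) = h_0(t) \exp\{\gamma'w_i + \alpha\, m_i(t)\}} with
#' \eqn{m_i(t)} the subject's current log-biomarker trajectory value.  The
#' 2-d integral over the random effects is approximated by tensor
#' Gauss-Hermite quadrature, by default centered and scaled at each
#' subject's longitudinal posterior (pseudo-adaptive), which makes the rule
#' exact in the severed-link case (`alpha = 0`).
#'
#' @param params a [joint_parameters()] object.
#' @param cohort preprocessed cohort.
#' @param outcome `"death"` or `"intervention"` (selects the status
#'   column).
#' @param nodes Gauss-Hermite nodes per random-effect dimension (>= 3).
#' @param adaptive center the quadrature at each subject's longitudinal
#'   posterior mode (default) rather than at the prior.
#' @param gl_points Gauss-Legendre points for the within-subject
#'   cumulative-hazard integral.
#' @param per_subject return the vector of per-subject contributions
#'   instead of their sum.
#' @return scalar log-likelihood (or vector if `per_subject`).
#' @export
joint_loglik <- function(params, cohort, outcome = "death", nodes = 15L,
                         adaptive = TRUE, gl_points = 15L,
                         per_subject = FALSE) {
  if (nodes < 3) dynjm_error("nodes must be >= 3", "dynjm_domain_error")
  dd <- long_design(cohort)
  sv <- surv_design(cohort$survival, outcome)
  gh <- gh_grid(nodes)
  gl <- gl_unit(gl_points)
  ll <- jm_theta_loglik(params_to_theta(params), dd, sv, gh, gl, adaptive)
  if (per_subject) ll else sum(ll)
}

jm_theta_loglik <- function(theta, dd, sv, gh, gl, adaptive = TRUE) {
  L <- matrix(c(exp(theta[9]), theta[10], 0, exp(theta[11])), 2, 2)
  jm_loglik_subj_cpp(theta[PAR_IDX$beta], L, exp(theta[PAR_IDX$lsig]),
                     theta[PAR_IDX$gamma], theta[PAR_IDX$alpha],
                     exp(theta[PAR_IDX$lshape]), exp(theta[PAR_IDX$lscale]),
                     dd$y, dd$X, dd$Z, dd$sidx, dd$x0, TIME_COL - 1L,
                     sv$W, sv$Tobs, sv$delta, gh$x, gh$logw, gh$sq,
                     gl$u, gl$w, adaptive)
}

#' Fit a joint model for one outcome by maximum likelihood
#'
#' Maximizes [joint_loglik()] over all 21 parameters (longitudinal fixed
#' effects, log-Cholesky factor of `D`, log residual variance, survival
#' coefficients, association, log Weibull shape and scale), initialized
#' from a two-stage fit: the ML mixed model ([fit_lmm()]) followed by a
#' Weibull proportional-hazards regression (via [survival::survreg()]) on
#' the baseline covariates plus the BLUP-based current trajectory value at
#' the observed time.  The longitudinal parameters are re-estimated
#' jointly, so each outcome gets a true joint fit, not a two-stage one.
#'
#' @param cohort preprocessed cohort with at least one observed event for
#'   the outcome.
#' @param outcome `"death"` or `"intervention"`.
#' @param config list of estimation settings; recognized entries
#'   `nodes` (default 15), `adaptive` (TRUE), `gl_points` (15),
#'   `iter_max` (400), `rel_tol` (1e-10), `hessian` (TRUE: compute the
#'   observed-information covariance matrix), `init` (optional
#'   `jm_parameters` warm start, replacing the two-stage initializer).
#' @return object of class `jm_fit`: `params` ([joint_parameters()]),
#'   `theta` (working-scale vector), `vcov` (inverse observed information
#'   on the working scale; `beta`, `gamma`, `alpha` entries are directly
#'   interpretable), `loglik`, `loglik_init`, `outcome`, `quadrature`,
#'   `converged`, `scaling_constants`.
#' @export
fit_joint <- function(cohort, outcome = c("death", "intervention"),
                      config = list()) {
  outcome <- match.arg(outcome)
  cfg <- modifyList(list(nodes = 15L, adaptive = TRUE, gl_points = 15L,
                         iter_max = 400L, rel_tol = 1e-10, hessian = TRUE,
                         grad = "central", init = NULL), config)
  dd <- long_design(cohort)
  sv <- surv_design(cohort$survival, outcome)
  if (sum(sv$delta) < 1)
    dynjm_error(sprintf("no observed %s events", outcome),
                "dynjm_degenerate_outcome_error")
  gh <- gh_grid(cfg$nodes)
  gl <- gl_unit(cfg$gl_points)

  init <- if (is.null(cfg$init)) two_stage_init(cohort, dd, sv) else cfg$init
  theta0 <- params_to_theta(init)
  negll <- function(theta) {
    v <- -sum(jm_theta_loglik(theta, dd, sv, gh, gl, cfg$adaptive))
    if (!is.finite(v)) 1e10 else v
  }
  grad <- if (identical(cfg$grad, "forward"))
    function(theta) grad_forward(negll, theta)
  else function(theta) grad_central(negll, theta)
  opt <- nlminb(theta0, negll, gradient = grad,
                control = list(iter.max = cfg$iter_max, eval.max = 4 * cfg$iter_max,
                               rel.tol = cfg$rel_tol))
  theta <- opt$par
  if (!is.finite(opt$objective))
    dynjm_error(sprintf("joint model did not converge (%s); |grad| = %.3g",
                        opt$message, max(abs(grad(theta)))),
                "dynjm_convergence_error")
  vc <- NULL
  if (isTRUE(cfg$hessian)) {
    H <- hessian_central(negll, theta)
    vc <- tryCatch(solve(H), error = function(e)
      solve(H + diag(1e-6, length(theta))))
    vc <- (vc + t(vc)) / 2
    dimnames(vc) <- list(theta_names(), theta_names())
  }
  structure(list(params = theta_to_params(theta), theta = theta,
                 vcov = vc, loglik = -opt$objective,
                 loglik_init = -negll(theta0), outcome = outcome,
                 quadrature = cfg$nodes, adaptive = cfg$adaptive,
                 gl_points = cfg$gl_points,
                 converged = opt$convergence == 0,
                 iterations = opt$iterations,
                 scaling_constants = cohort$scaling_constants,
                 n_subjects = dd$n, n_events = sum(sv$delta)),
            class = "jm_fit")
}

# ML mixed model, then Weibull PH (AFT fit converted to the PH scale) with
# the BLUP current value at the observed time as a fixed covariate
two_stage_init <- function(cohort, dd, sv) {
  lmm <- fit_lmm(cohort)
  mhat <- as.numeric(dd$x0 %*% lmm$beta) +
    lmm$beta[TIME_COL] * sv$Tobs + lmm$blups[, 1] + lmm$blups[, 2] * sv$Tobs
  sr <- tryCatch(
    survival::survreg(survival::Surv(sv$Tobs, sv$delta) ~ sv$W + mhat,
                      dist = "weibull"),
    error = function(e) NULL)
  if (!is.null(sr) && all(is.finite(coef(sr))) && is.finite(sr$scale)) {
    s <- sr$scale
    co <- coef(sr)
    gamma <- -co[2:7] / s
    alpha <- -co[8] / s
    shape <- 1 / s
    scale <- exp(co[1])
  } else {
    gamma <- rep(0, 6); alpha <- 0; shape <- 1
    scale <- sum(sv$Tobs) / max(sum(sv$delta), 1)
  }
  joint_parameters(lmm$beta, lmm$D, lmm$sigma2, gamma, alpha,
                   list(family = "weibull", shape = shape,
                        scale = max(scale, 1e-3)))
}

grad_forward <- function(f, x, h = 1e-6) {
  hh <- h * pmax(1, abs(x))
  f0 <- f(x)
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- hh[i]
    (f(x + e) - f0) / hh[i]
  }, numeric(1))
}

grad_central <- function(f, x, h = 1e-5) {
  hh <- h * pmax(1, abs(x))
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- hh[i]
    (f(x + e) - f(x - e)) / (2 * hh[i])
  }, numeric(1))
}

hessian_central <- function(f, x, h = 1e-4) {
  p <- length(x)
  hh <- h * pmax(1, abs(x))
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- hh[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh[i]^2
    if (i < p) for (j in seq.int(i + 1, p)) {
      ej <- numeric(p); ej[j] <- hh[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hh[i] * hh[j])
    }
  }
  H
}

#' Hazard-ratio summary table of a joint model fit
#'
#' One row per survival-submodel term: the current-value association first,
#' then the baseline covariates.  `HR = exp(coef)` rounded to 2 decimals
#' for display; `p` is the two-sided Wald test.
#'
#' @param fit a `jm_fit` (or a `jm_parameters` object, in which case `se`
#'   and `p` are `NA`).
#' @return data frame with columns term, coef, HR, se, p.
#' @export
hazard_ratio_table <- function(fit) {
  if (inherits(fit, "jm_parameters")) {
    coefs <- c(fit$alpha, fit$gamma)
    se <- rep(NA_real_, 7)
  } else {
    coefs <- c(fit$params$alpha, fit$params$gamma)
    se <- if (is.null(fit$vcov)) rep(NA_real_, 7) else
      sqrt(diag(fit$vcov)[c(PAR_IDX$alpha, PAR_IDX$gamma)])
  }
  data.frame(term = c("value_log_current", SURV_TERMS),
             coef = unname(coefs), HR = round(exp(unname(coefs)), 2),
             se = unname(se), p = 2 * pnorm(-abs(unname(coefs) / se)),
             row.names = NULL)
}

#' Conditional survival function given the random effects
#'
#' \eqn{S(t \mid b) = \exp\{-\int_0^t h(s \mid b)\, ds\}} with the
#' cumulative hazard computed by adaptive Gauss-Kronrod integration
#' (absolute tolerance 1e-8).
#'
#' @param params a [joint_parameters()] object.
#' @param covariates named raw-scale baseline covariates (see
#'   [predict_trajectory()]).
#' @param b length-2 random-effect value (intercept, slope).
#' @param t years (>= 0); may be a vector.
#' @param scaling_constants named SDs for lvef/creatinine (training
#'   constants of the fit the parameters came from).
#' @return survival probabilities in (0, 1].
#' @export
conditional_survival <- function(params, covariates, b, t,
                                 scaling_constants) {
  if (any(t < 0)) dynjm_error("t must be >= 0", "dynjm_domain_error")
  x0 <- subject_x0(covariates, scaling_constants)
  w <- x0[1, c("ava", "age", "male", "symptoms", "lvef_scaled",
               "creatinine_scaled")]
  eta <- sum(params$gamma * w)
  c0 <- sum(x0[1, ] * params$beta) + b[1]
  c1 <- params$beta[[TIME_COL]] + b[2]
  k <- params$h0$shape; lam <- params$h0$scale; a <- params$alpha
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    H <- integrate(function(s)
      (k / lam) * (s / lam)^(k - 1) * exp(eta + a * (c0 + c1 * s)),
      0, tt, abs.tol = 1e-8, rel.tol = 1e-10)$value
    exp(-H)
  }, numeric(1))
}

# vectorized cumulative hazard over random-effect draws (rows of B);
# Gauss-Legendre after the power substitution, same rule as the likelihood
cum_hazard_draws <- function(alpha, shape, scale, eta, c0base, c1base, B,
                             t, gl) {
  c0 <- c0base + B[, 1]
  c1 <- c1base + B[, 2]
  tk <- (t / scale)^shape
  E <- exp(outer(c1 * (alpha * t), gl$u^(1 / shape)))   # draws x K
  as.numeric(exp(eta + alpha * c0) * tk * (E %*% gl$w))
}

#' Serialize a joint model fit to a plain-text parameter file
#'
#' Versioned JSON carrying the working-scale parameter vector, covariance
#' matrix, scaling constants and estimation settings; [read_joint_fit()]
#' restores an object usable by the prediction functions.
#'
#' @param fit a `jm_fit`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_joint_fit <- function(fit, path) {
  obj <- list(format = "dynjm-fit", version = 1L, outcome = fit$outcome,
              theta = fit$theta, vcov = fit$vcov, loglik = fit$loglik,
              quadrature = fit$quadrature, adaptive = fit$adaptive,
              gl_points = fit$gl_points, converged = fit$converged,
              scaling_constants = as.list(fit$scaling_constants))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_joint_fit
#' @export
read_joint_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dynjm-fit"))
    dynjm_error("not a dynjm fit file", "dynjm_io_error")
  theta <- as.numeric(obj$theta)
  vc <- if (!is.null(obj$vcov)) as.matrix(obj$vcov) else NULL
  structure(list(params = theta_to_params(theta), theta = theta, vcov = vc,
                 loglik = obj$loglik, outcome = obj$outcome,
                 quadrature = obj$quadrature, adaptive = obj$adaptive,
                 gl_points = obj$gl_points, converged = obj$converged,
                 scaling_constants = unlist(obj$scaling_constants)),
            class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat(sprintf("Joint model fit (outcome: %s)\n", x$outcome))
  cat(sprintf("  subjects %d, events %d, logLik %.3f, GH nodes %d%s\n",
              x$n_subjects %||% NA, x$n_events %||% NA, x$loglik,
              x$quadrature, if (isTRUE(x$adaptive)) " (adaptive)" else ""))
  cat(sprintf("  Weibull baseline: shape %.3f, scale %.3f\n",
              x$params$h0$shape, x$params$h0$scale))
  print(transform(hazard_ratio_table(x), coef = round(coef, 3),
                  se = round(se, 3), p = round(p, 4)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
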