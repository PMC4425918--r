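#' Maximum-likelihood linear mixed model for the log biomarker
#'
#' Fits, by maximum likelihood, the linear mixed-effects model
#' \deqn{y_i(t) = x_i(t)'\beta + b_{0i} + b_{1i} t + \varepsilon_{ij},
#'   \quad b_i \sim N(0, D), \ \varepsilon \sim N(0, \sigma^2),}
#' for the natural-log biomarker, with fixed effects for time (years) and
#' the baseline covariates (AVA, age, symptoms, gender, SD-scaled LVEF and
#' SD-scaled creatinine) and correlated random intercept and slope.
#'
#' The 2x2 random-effects covariance `D` is parameterized through its
#' log-Cholesky factor relative to the residual variance, the fixed effects
#' and residual variance are profiled out, and the remaining 3-parameter
#' profile deviance is minimized by quasi-Newton iteration.  ML (not REML)
#' is used so the fit can initialize the joint model, whose likelihood is
#' ML-based.
#'
#' @param cohort a preprocessed [new_cohort()] object (`value_log` and the
#'   scaled covariates present).
#' @return An object of class `jm_lmm` with elements `beta` (named fixed
#'   effects), `D` (2x2 covariance), `sigma2`, `loglik`, `se_beta`,
#'   `blups` (per-subject posterior mean random effects, subjects in
#'   survival-table order), `fitted_psi` (working log-Cholesky parameters)
#'   and `scaling_constants`.
#' @export
fit_lmm <- function(cohort) {
  dd <- long_design(cohort)
  if (dd$n < 2)
    dynjm_error("need >= 2 subjects", "dynjm_domain_error")
  qrX <- qr(dd$X)
  if (qrX$rank < ncol(dd$X)) {
    bad <- colnames(dd$X)[qrX$pivot[(qrX$rank + 1):ncol(dd$X)]]
    dynjm_error(paste("design matrix rank-deficient; collinear column(s):",
                      paste(bad, collapse = ", ")),
                "dynjm_singular_design_error")
  }
  blocks <- lmm_blocks(dd)

  obj <- function(psi) lmm_profile_dev(psi, blocks)$dev
  fit <- nlminb(c(-0.5, 0, -0.5), obj,
                control = list(rel.tol = 1e-12, iter.max = 500L))
  if (fit$convergence != 0 && fit$objective > obj(fit$par) + 1e-6)
    dynjm_error(paste("LMM optimizer did not converge:", fit$message),
                "dynjm_convergence_error")
  out <- lmm_profile_dev(fit$par, blocks, details = TRUE)
  names(out$beta) <- LMM_TERMS
  names(out$se_beta) <- LMM_TERMS
  dimnames(out$D) <- list(c("(Intercept)", "time"), c("(Intercept)", "time"))
  rownames(out$blups) <- cohort$survival$subject_id
  structure(c(out, list(fitted_psi = fit$par,
                        scaling_constants = cohort$scaling_constants,
                        n_subjects = dd$n, n_obs = length(dd$y))),
            class = "jm_lmm")
}

lmm_blocks <- function(dd) {
  n <- dd$n
  lapply(seq_len(n), function(i) {
    r <- seq.int(dd$sidx[i] + 1L, length.out = dd$sidx[i + 1L] - dd$sidx[i])
    list(y = dd$y[r], X = dd$X[r, , drop = FALSE], Z = dd$Z[r, , drop = FALSE])
  })
}

# psi = log-Cholesky parameters of Dstar = D / sigma2 (l11, l21, l22 with
# log on the diagonal); beta and sigma2 are profiled out in closed form
lmm_profile_dev <- function(psi, blocks, details = FALSE) {
  L <- matrix(c(exp(psi[1]), psi[2], 0, exp(psi[3])), 2, 2)
  Dstar <- L %*% t(L)
  p <- ncol(blocks[[1]]$X)
  XtVX <- matrix(0, p, p); XtVy <- numeric(p)
  Vinv <- vector("list", length(blocks)); ldet <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ni <- length(b$y)
    if (ni == 0L) { Vinv[[i]] <- matrix(0, 0, 0); next }
    V <- b$Z %*% Dstar %*% t(b$Z) + diag(ni)
    ch <- chol(V)
    ldet <- ldet + 2 * sum(log(diag(ch)))
    Vi <- chol2inv(ch)
    Vinv[[i]] <- Vi
    XtVX <- XtVX + crossprod(b$X, Vi %*% b$X)
    XtVy <- XtVy + crossprod(b$X, Vi %*% b$y)
  }
  beta <- solve(XtVX, XtVy)
  rss <- 0; N <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (!length(b$y)) next
    r <- b$y - b$X %*% beta
    rss <- rss + crossprod(r, Vinv[[i]] %*% r)
    N <- N + length(b$y)
  }
  sigma2 <- max(as.numeric(rss) / N, 1e-10)
  dev <- N * log(2 * pi * sigma2) + ldet + as.numeric(rss) / sigma2
  if (!details) return(list(dev = dev))
  se_beta <- sqrt(diag(solve(XtVX)) * sigma2)
  blups <- t(vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (!length(b$y)) return(c(0, 0))
    as.numeric(Dstar %*% crossprod(b$Z, Vinv[[i]] %*% (b$y - b$X %*% beta)))
  }, numeric(2)))
  list(dev = dev, beta = as.numeric(beta), D = sigma2 * Dstar,
       sigma2 = sigma2, loglik = -dev / 2, se_beta = se_beta, blups = blups)
}

#' Marginal log-likelihood of a linear mixed model at given parameters
#'
#' Direct evaluation of the Gaussian marginal likelihood
#' \eqn{\prod_i N(y_i; X_i\beta, Z_i D Z_i' + \sigma^2 I)}; used to verify
#' that the joint likelihood factorizes when the association is severed.
#'
#' @param cohort preprocessed cohort.
#' @param beta,D,sigma2 parameter values.
#' @return scalar log-likelihood.
#' @export
lmm_marginal_loglik <- function(cohort, beta, D, sigma2) {
  dd <- long_design(cohort)
  ll <- 0
  for (b in lmm_blocks(dd)) {
    ni <- length(b$y)
    if (!ni) next
    S <- b$Z %*% D %*% t(b$Z) + sigma2 * diag(ni)
    r <- b$y - b$X %*% beta
    ch <- chol(S)
    ll <- ll - 0.5 * (ni * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        sum(backsolve(ch, r, transpose = TRUE)^2))
  }
  ll
}

#' Predict a subject's log-biomarker trajectory
#'
#' Returns \eqn{x(t)'\hat\beta + \hat b_0 + \hat b_1 t} with \eqn{\hat b}
#' the subject's empirical-Bayes posterior mean given the supplied
#' measurement history (the zero vector for a subject with no
#' measurements, i.e. the population-mean trajectory).
#'
#' @param fit a `jm_lmm`.
#' @param covariates named list/vector with `ava`, `age`, `symptoms`,
#'   `male`, `lvef`, `creatinine` on the raw scale (scaled internally
#'   using the fit's stored training SDs).
#' @param measurements optional data frame with columns `time` and `value`
#'   (pg/ml) or `value_log`.
#' @param times vector of years (>= 0) at which to predict.
#' @return numeric vector of predicted `value_log` at `times`.
#' @export
predict_trajectory <- function(fit, covariates, measurements = NULL,
                               times) {
  if (any(times < 0))
    dynjm_error("prediction times must be >= 0", "dynjm_domain_error")
  x0 <- subject_x0(covariates, fit$scaling_constants)
  b <- c(0, 0)
  if (!is.null(measurements) && nrow(measurements) > 0) {
    yl <- if ("value_log" %in% names(measurements)) measurements$value_log
    else log(measurements$value)
    Z <- cbind(1, measurements$time)
    X <- x0[rep(1, nrow(Z)), , drop = FALSE]
    X[, TIME_COL] <- measurements$time
    S <- Z %*% fit$D %*% t(Z) + fit$sigma2 * diag(nrow(Z))
    b <- as.numeric(fit$D %*% crossprod(Z, solve(S, yl - X %*% fit$beta)))
  }
  Xt <- x0[rep(1, length(times)), , drop = FALSE]
  Xt[, TIME_COL] <- times
  as.numeric(Xt %*% fit$beta) + b[1] + b[2] * times
}

# one-row baseline design for a new subject, scaling raw lvef/creatinine
# by the training-cohort SDs
subject_x0 <- function(covariates, scaling_constants) {
  covariates <- as.list(covariates)
  need <- c("ava", "age", "symptoms", "male", "lvef", "creatinine")
  miss <- setdiff(need, names(covariates))
  if (length(miss))
    dynjm_error(paste("missing covariate(s):", paste(miss, collapse = ", ")),
                "dynjm_schema_error")
  sc <- scaling_constants
  if (!all(c("lvef", "creatinine") %in% names(sc)))
    dynjm_error("fit carries no scaling constants for lvef/creatinine",
                "dynjm_schema_error")
  matrix(c(1, 0, covariates$ava, covariates$age, covariates$symptoms,
           covariates$male, covariates$lvef / sc[["lvef"]],
           covariates$creatinine / sc[["creatinine"]]),
         1, 8, dimnames = list(NULL, LMM_TERMS))
}

#' Export an LMM fit summary in coefficient-table layout
#'
#' @param fit a `jm_lmm`.
#' @return data frame with columns term, coef, se, p (two-sided Wald).
#' @export
lmm_summary_table <- function(fit) {
  z <- fit$beta / fit$se_beta
  data.frame(term = names(fit$beta), coef = fit$beta, se = fit$se_beta,
             p = 2 * pnorm(-abs(z)), row.names = NULL)
}

#' @export
print.jm_lmm <- function(x, ...) {
  cat("Linear mixed model (ML) for log biomarker\n")
  cat(sprintf("  subjects %d, observations %d, logLik %.3f\n",
              x$n_subjects, x$n_obs, x$loglik))
  tab <- lmm_summary_table(x)
  tab[-1] <- round(tab[-1], 4)
  print(tab)
  cat(sprintf("  random effects SD: intercept %.3f, slope %.3f (corr %.2f); residual SD %.3f\n",
              sqrt(x$D[1, 1]), sqrt(x$D[2, 2]),
              x$D[1, 2] / sqrt(x$D[1, 1] * x$D[2, 2]), sqrt(x$sigma2)))
  invisible(x)
}
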