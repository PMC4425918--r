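#' Time-dependent ROC for dynamic predictions with a fixed window
#'
#' At landmark time t, every subject still at risk is scored with the
#' model-based risk \eqn{1 - \pi(t + dt \mid t)} computed from their own
#' measurement history up to t (deterministic first-order estimator).
#' Cases are subjects whose event falls in (t, t + dt]; controls are
#' subjects known event-free beyond t + dt; subjects whose follow-up ends
#' inside the window without the event (censoring or the competing
#' outcome) are excluded.  The ROC curve is a threshold sweep over the
#' observed scores and the AUC is the trapezoid area, which equals the
#' Mann-Whitney concordance statistic with ties counted 1/2.
#'
#' @param fit a `jm_fit` for the outcome of interest.
#' @param cohort preprocessed cohort to score.
#' @param t landmark time in years.
#' @param dt prediction-window length in years; the half-year default
#'   matches the cohort's visit spacing.
#' @param nodes Gauss-Hermite nodes used when scoring.
#' @return object of class `jm_roc`: `t`, `dt`, `fpr`, `tpr`, `auc`,
#'   `n_cases`, `n_controls`, `scores` (data frame of subject scores and
#'   case status).
#' @export
dynamic_roc <- function(fit, cohort, t = 1, dt = 0.5, nodes = 9L) {
  surv <- cohort$survival
  sv <- surv_design(surv, fit$outcome)
  at_risk <- surv$obs_time > t
  is_case <- at_risk & sv$delta == 1 & surv$obs_time <= t + dt
  is_control <- surv$obs_time > t + dt
  keep <- which(is_case | is_control)
  if (sum(is_case) < 1 || sum(is_control) < 1)
    dynjm_error(sprintf("window (%g, %g] degenerate: %d cases, %d controls",
                        t, t + dt, sum(is_case), sum(is_control)),
                "dynjm_degeneracy_error")
  long <- cohort$longitudinal
  scores <- vapply(keep, function(i) {
    sid <- surv$subject_id[i]
    ms <- long[long$subject_id == sid & long$time <= t,
               c("time", "value"), drop = FALSE]
    h <- subject_history(as.list(surv[i, c("ava", "age", "symptoms", "male",
                                           "lvef", "creatinine")]),
                         ms, t = t)
    1 - predict_event_free(fit, h, u_grid = t + dt, mode = "first_order",
                           nodes = nodes)$pi
  }, numeric(1))
  sc <- data.frame(subject_id = surv$subject_id[keep], score = scores,
                   case = as.integer(is_case[keep]))
  roc <- roc_points(sc$score[sc$case == 1], sc$score[sc$case == 0])
  structure(list(t = t, dt = dt, fpr = roc$fpr, tpr = roc$tpr,
                 auc = roc$auc, n_cases = sum(sc$case),
                 n_controls = sum(1 - sc$case), scores = sc),
            class = "jm_roc")
}

# threshold-sweep ROC and trapezoid AUC from case/control scores
roc_points <- function(case_scores, control_scores) {
  thr <- c(Inf, sort(unique(c(case_scores, control_scores)),
                     decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(cc) mean(case_scores >= cc), numeric(1))
  fpr <- vapply(thr, function(cc) mean(control_scores >= cc), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' @export
print.jm_roc <- function(x, ...) {
  cat(sprintf(
    "Time-dependent ROC at t = %g y, window %g y: AUC = %.3f (%d cases, %d controls)\n",
    x$t, x$dt, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
plot.jm_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", lwd = 2, xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("AUC = %.3f (t = %g, dt = %g)",
                                x$auc, x$t, x$dt), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Subject-level bootstrap internal validation of discrimination
#'
#' Draws B bootstrap resamples of whole subjects (with replacement,
#' keeping each subject's full measurement history intact), refits the
#' joint model on each resample (warm-started from the original-data fit,
#' reduced quadrature allowed), scores the resample with [dynamic_roc()]
#' and records the apparent AUC.  Resamples whose window is degenerate
#' (no cases or no controls) are skipped and redrawn, up to a cap.
#'
#' @param cohort preprocessed cohort.
#' @param outcome `"death"` or `"intervention"`.
#' @param t,dt landmark and window (years).
#' @param B number of bootstrap resamples.
#' @param seed integer seed; the report is reproducible given the seed.
#' @param config estimation settings for the resample refits (see
#'   [fit_joint()]); `nodes` defaults to 7 and the information matrix is
#'   skipped.  Entry `fit` may carry a pre-computed full-data `jm_fit`
#'   to warm-start from.
#' @return object of class `jm_bootstrap`: `B`, `auc_mean`, `auc_sd`,
#'   `auc_samples`, `seed`, `n_skipped`, `auc_apparent` (full-data AUC).
#' @export
bootstrap_validate <- function(cohort, outcome = c("death", "intervention"),
                               t = 1, dt = 0.5, B = 50L, seed = 1L,
                               config = list()) {
  outcome <- match.arg(outcome)
  if (B < 1) dynjm_error("B must be >= 1", "dynjm_domain_error")
  cfg <- modifyList(list(nodes = 7L, hessian = FALSE, roc_nodes = 9L),
                    config)
  base_fit <- cfg$fit
  if (is.null(base_fit))
    base_fit <- fit_joint(cohort, outcome,
                          config = list(nodes = cfg$nodes, hessian = FALSE))
  apparent <- dynamic_roc(base_fit, cohort, t, dt, nodes = cfg$roc_nodes)$auc
  refit_cfg <- list(nodes = cfg$nodes, hessian = FALSE,
                    init = base_fit$params)

  set.seed(seed)
  n <- nrow(cohort$survival)
  auc <- numeric(B)
  skipped <- 0L; b <- 1L; cap <- 20L * B
  while (b <= B) {
    if (skipped + b > cap)
      dynjm_error("too many degenerate bootstrap resamples",
                  "dynjm_degeneracy_error")
    idx <- sample.int(n, n, replace = TRUE)
    boot <- resample_cohort(cohort, idx)
    a <- tryCatch({
      bf <- fit_joint(boot, outcome, config = refit_cfg)
      dynamic_roc(bf, boot, t, dt, nodes = cfg$roc_nodes)$auc
    }, dynjm_error = function(e) NA_real_)
    if (is.na(a)) { skipped <- skipped + 1L; next }
    auc[b] <- a; b <- b + 1L
  }
  structure(list(B = B, auc_mean = mean(auc), auc_sd = sd(auc),
                 auc_samples = auc, seed = seed, n_skipped = skipped,
                 auc_apparent = apparent, outcome = outcome, t = t,
                 dt = dt),
            class = "jm_bootstrap")
}

# resampled subjects get fresh ids so repeated draws stay distinct clusters
resample_cohort <- function(cohort, idx) {
  surv <- cohort$survival[idx, , drop = FALSE]
  new_id <- sprintf("B%05d", seq_along(idx))
  pieces <- lapply(seq_along(idx), function(k) {
    rows <- cohort$longitudinal[
      cohort$longitudinal$subject_id == surv$subject_id[k], , drop = FALSE]
    if (nrow(rows)) rows$subject_id <- new_id[k]
    rows
  })
  surv$subject_id <- new_id
  out <- new_cohort(do.call(rbind, pieces), surv)
  out$scaling_constants <- cohort$scaling_constants
  out
}

#' @export
print.jm_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap validation (%s, t = %g, dt = %g, B = %d):\n", x$outcome,
    x$t, x$dt, x$B))
  cat(sprintf("  apparent AUC %.3f; bootstrap mean %.3f (SD %.3f), %d resamples skipped\n",
              x$auc_apparent, x$auc_mean, x$auc_sd, x$n_skipped))
  invisible(x)
}
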