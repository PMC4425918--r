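# Model frames shared by the longitudinal, joint and prediction code.
#
# Fixed effects of the longitudinal submodel, in this order:
#   intercept, time, ava, age, symptoms, male, lvef_scaled, creatinine_scaled
# Random effects: intercept + slope on time (linear trajectories).
# Survival covariates (gamma), in this order:
#   ava, age, male, symptoms, lvef_scaled, creatinine_scaled

LMM_TERMS  <- c("(Intercept)", "time", "ava", "age", "symptoms", "male",
                "lvef_scaled", "creatinine_scaled")
SURV_TERMS <- c("ava", "age", "male", "symptoms", "lvef_scaled",
                "creatinine_scaled")
TIME_COL <- 2L  # position of the time slope within LMM_TERMS

# baseline (time-invariant) part of the longitudinal fixed design for a
# one-row-per-subject covariate table, evaluated at time = 0
baseline_design <- function(surv) {
  need <- c("ava", "age", "symptoms", "male", "lvef_scaled",
            "creatinine_scaled")
  miss <- setdiff(need, names(surv))
  if (length(miss))
    dynjm_error(paste("cohort not preprocessed; missing:",
                      paste(miss, collapse = ", ")), "dynjm_schema_error")
  cbind(1, 0, surv$ava, surv$age, surv$symptoms, surv$male,
        surv$lvef_scaled, surv$creatinine_scaled)
}

# stacked longitudinal design: y, X (N x 8), Z (N x 2), subject block index
long_design <- function(cohort) {
  surv <- cohort$survival
  long <- cohort$longitudinal
  if (is.null(long$value_log))
    dynjm_error("cohort not preprocessed (value_log missing); run preprocess_cohort()",
                "dynjm_schema_error")
  x0 <- baseline_design(surv)
  colnames(x0) <- LMM_TERMS
  idx <- match(long$subject_id, surv$subject_id)
  X <- x0[idx, , drop = FALSE]
  X[, TIME_COL] <- long$time
  Z <- cbind(1, long$time)
  # 0-based start offsets of each subject's block (subjects in surv order,
  # possibly with empty blocks); longitudinal rows are sorted by subject
  ord <- order(idx)
  cnt <- tabulate(idx, nbins = nrow(surv))
  sidx <- c(0L, cumsum(cnt))
  list(y = long$value_log[ord], X = X[ord, , drop = FALSE],
       Z = Z[ord, , drop = FALSE], sidx = as.integer(sidx),
       x0 = x0, n = nrow(surv))
}

surv_design <- function(surv, outcome = c("death", "intervention")) {
  outcome <- match.arg(outcome)
  W <- cbind(surv$ava, surv$age, surv$male, surv$symptoms,
             surv$lvef_scaled, surv$creatinine_scaled)
  colnames(W) <- SURV_TERMS
  delta <- if (outcome == "death") surv$status_death else
    surv$status_intervention
  list(W = W, Tobs = surv$obs_time, delta = as.numeric(delta),
       outcome = outcome)
}

# tensor-product Gauss-Hermite grid over the 2-d random effect
gh_grid <- function(nodes) {
  gh <- pracma::gaussHermite(nodes)
  x <- as.matrix(expand.grid(gh$x, gh$x))
  w <- as.vector(outer(gh$w, gh$w))
  list(x = x, logw = log(w), sq = rowSums(x^2))
}

# Gauss-Legendre rule mapped to (0, 1); used inside the cumulative hazard
gl_unit <- function(k = 15L) {
  gl <- pracma::gaussLegendre(k, 0, 1)
  list(u = gl$x, w = gl$w)
}
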