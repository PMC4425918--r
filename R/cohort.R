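#' @useDynLib dynjm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd qnorm pnorm rnorm runif rbinom rchisq dnorm
#'   integrate optim nlminb uniroot quantile setNames coef
#' @importFrom utils read.csv write.csv modifyList head tail
NULL

# condition constructors: every validation failure carries a typed class so
# callers (and tests) can distinguish schema vs link vs domain problems
dynjm_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "dynjm_error")))
}

LONG_COLS <- c("subject_id", "time", "value")
SURV_COLS <- c("subject_id", "obs_time", "status_death", "status_intervention",
               "ava", "age", "symptoms", "male", "lvef", "creatinine")

#' Construct and validate a linked longitudinal + survival cohort
#'
#' A cohort bundles the two tables of a longitudinal-survival study: a long
#' table of per-visit biomarker measurements (one row per assay) and a
#' one-row-per-subject survival table carrying the observed event/censoring
#' time, one status indicator per outcome (death; aortic-valve
#' intervention) and the baseline covariates.  Link integrity (every
#' longitudinal subject present in the survival table, no measurement after
#' the subject's observed time) is enforced on construction.
#'
#' @param longitudinal data frame with columns `subject_id`, `time` (years
#'   since baseline, >= 0), `value` (biomarker in pg/ml, > 0) and
#'   optionally `value_log`.
#' @param survival data frame with columns `subject_id` (unique),
#'   `obs_time` (years, > 0), `status_death`, `status_intervention` (0/1;
#'   1 = event observed), `ava` (cm^2), `age` (years), `symptoms` (0/1),
#'   `male` (0/1), `lvef` (percent), `creatinine` (micromol/L).
#' @param scaling_constants named numeric vector of the standard deviations
#'   used by [scale_by_sd()]; recorded for reproducible scaling of new
#'   subjects at prediction time.
#' @return An object of class `jm_cohort`: a list with elements
#'   `longitudinal`, `survival` and `scaling_constants`.  Longitudinal rows
#'   are sorted by subject then time.
#' @export
new_cohort <- function(longitudinal, survival, scaling_constants = numeric(0)) {
  check_columns(longitudinal, LONG_COLS, "longitudinal")
  check_columns(survival, SURV_COLS, "survival")
  for (col in c("time", "value")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(longitudinal[[col]]))))
    if (length(bad))
      dynjm_error(sprintf("non-numeric %s in longitudinal rows: %s",
                          col, paste(bad, collapse = ", ")),
                  "dynjm_parse_error", rows = bad)
    longitudinal[[col]] <- as.numeric(longitudinal[[col]])
  }
  num_surv <- setdiff(SURV_COLS, "subject_id")
  for (col in num_surv) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(survival[[col]]))))
    if (length(bad))
      dynjm_error(sprintf("non-numeric %s in survival rows: %s",
                          col, paste(bad, collapse = ", ")),
                  "dynjm_parse_error", rows = bad)
    survival[[col]] <- as.numeric(survival[[col]])
  }
  longitudinal$subject_id <- as.character(longitudinal$subject_id)
  survival$subject_id <- as.character(survival$subject_id)

  if (anyDuplicated(survival$subject_id))
    dynjm_error("duplicated subject_id in survival table",
                "dynjm_schema_error")
  if (any(survival$obs_time <= 0))
    dynjm_error("obs_time must be > 0", "dynjm_domain_error")
  for (col in c("status_death", "status_intervention", "symptoms", "male"))
    if (!all(survival[[col]] %in% c(0, 1)))
      dynjm_error(sprintf("%s must be coded 0/1", col), "dynjm_domain_error")
  if (any(longitudinal$time < 0))
    dynjm_error("longitudinal time must be >= 0", "dynjm_domain_error")
  if (any(longitudinal$value <= 0))
    dynjm_error(
      sprintf("biomarker value <= 0 (log undefined) in rows: %s",
              paste(which(longitudinal$value <= 0), collapse = ", ")),
      "dynjm_domain_error")

  orphan <- setdiff(longitudinal$subject_id, survival$subject_id)
  if (length(orphan))
    dynjm_error(sprintf("longitudinal subjects missing from survival table: %s",
                        paste(orphan, collapse = ", ")),
                "dynjm_link_error", ids = orphan)

  longitudinal <- longitudinal[order(longitudinal$subject_id,
                                     longitudinal$time), , drop = FALSE]
  rownames(longitudinal) <- NULL
  rownames(survival) <- NULL

  # measurements at exactly obs_time are allowed (closed interval)
  last <- tapply(longitudinal$time, longitudinal$subject_id, max)
  ot <- setNames(survival$obs_time, survival$subject_id)
  late <- names(last)[last > ot[names(last)] + 1e-12]
  if (length(late))
    dynjm_error(sprintf("measurements after obs_time for subjects: %s",
                        paste(late, collapse = ", ")),
                "dynjm_link_error", ids = late)

  structure(list(longitudinal = longitudinal, survival = survival,
                 scaling_constants = scaling_constants),
            class = "jm_cohort")
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    dynjm_error(sprintf("%s table is missing column(s): %s",
                        what, paste(miss, collapse = ", ")),
                "dynjm_schema_error", columns = miss)
  invisible(TRUE)
}

#' Load a cohort from two CSV files
#'
#' @param long_path path to the longitudinal CSV (header
#'   `subject_id,time,value`).
#' @param surv_path path to the survival/baseline CSV (header row naming
#'   the fields of [new_cohort()]).
#' @return a validated `jm_cohort`.
#' @export
load_cohort <- function(long_path, surv_path) {
  for (p in c(long_path, surv_path))
    if (!file.exists(p))
      dynjm_error(paste("file not found:", p), "dynjm_io_error")
  long <- read.csv(long_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  surv <- read.csv(surv_path, stringsAsFactors = FALSE,
                   colClasses = "character")
  new_cohort(long, surv)
}

#' Write a cohort to two CSV files
#'
#' Floats are written with full precision (15 significant digits) so a
#' write -> load round trip reproduces every field.
#'
#' @param cohort a `jm_cohort`.
#' @param long_path,surv_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, long_path, surv_path) {
  fmt <- function(df) {
    for (col in names(df))
      if (is.numeric(df[[col]])) df[[col]] <- format(df[[col]], digits = 15,
                                                     trim = TRUE,
                                                     scientific = FALSE)
    df
  }
  keep_long <- intersect(c(LONG_COLS, "value_log"), names(cohort$longitudinal))
  keep_surv <- intersect(c(SURV_COLS, "lvef_scaled", "creatinine_scaled"),
                         names(cohort$survival))
  write.csv(fmt(cohort$longitudinal[keep_long]), long_path, row.names = FALSE,
            quote = FALSE)
  write.csv(fmt(cohort$survival[keep_surv]), surv_path, row.names = FALSE,
            quote = FALSE)
  invisible(c(long_path, surv_path))
}

#' Natural-log transform of the biomarker
#'
#' Fills `value_log = log(value)`; the raw pg/ml column is retained.  The
#' natural (not base-10) logarithm is used throughout: the survival
#' submodel's association coefficient is then a log hazard ratio per unit
#' of log-biomarker, the conventional scale for BNP-type markers.
#'
#' @param cohort a `jm_cohort`.
#' @return the cohort with `value_log` filled.
#' @export
log_transform_biomarker <- function(cohort) {
  bad <- which(cohort$longitudinal$value <= 0)
  if (length(bad))
    dynjm_error(sprintf("value <= 0 in rows: %s", paste(bad, collapse = ", ")),
                "dynjm_domain_error", rows = bad)
  cohort$longitudinal$value_log <- log(cohort$longitudinal$value)
  cohort
}

#' Scale covariates by their sample standard deviation
#'
#' Divides each named survival-table covariate by its sample SD (n - 1
#' denominator) computed from this cohort, storing the result in
#' `<name>_scaled` and recording the SD in `scaling_constants` so new
#' subjects at prediction time are scaled by the training constants.
#'
#' @param cohort a `jm_cohort`.
#' @param covariates character vector of survival-table column names;
#'   default the two covariates conventionally SD-scaled in this analysis.
#' @param constants optional named numeric vector of SDs to use instead of
#'   recomputing (idempotent re-application).
#' @return the cohort with scaled columns and `scaling_constants` filled.
#' @export
scale_by_sd <- function(cohort, covariates = c("lvef", "creatinine"),
                        constants = NULL) {
  for (cov in covariates) {
    if (!cov %in% names(cohort$survival))
      dynjm_error(paste("unknown covariate:", cov), "dynjm_schema_error")
    s <- if (!is.null(constants) && cov %in% names(constants))
      constants[[cov]] else sd(cohort$survival[[cov]])
    if (!is.finite(s) || s <= 0)
      dynjm_error(sprintf("covariate %s has zero or undefined SD", cov),
                  "dynjm_degenerate_covariate_error")
    cohort$survival[[paste0(cov, "_scaled")]] <- cohort$survival[[cov]] / s
    cohort$scaling_constants[cov] <- s
  }
  cohort
}

#' Standard preprocessing: log biomarker + SD-scale covariates
#'
#' @inheritParams scale_by_sd
#' @return preprocessed `jm_cohort`.
#' @export
preprocess_cohort <- function(cohort, covariates = c("lvef", "creatinine"),
                              constants = NULL) {
  scale_by_sd(log_transform_biomarker(cohort), covariates, constants)
}

#' @export
print.jm_cohort <- function(x, ...) {
  cat("Linked longitudinal-survival cohort\n")
  cat(sprintf("  subjects:     %d\n", nrow(x$survival)))
  cat(sprintf("  measurements: %d\n", nrow(x$longitudinal)))
  cat(sprintf("  events:       %d deaths, %d interventions\n",
              sum(x$survival$status_death), sum(x$survival$status_intervention)))
  if (length(x$scaling_constants))
    cat("  scaling SDs:  ",
        paste(sprintf("%s=%.4g", names(x$scaling_constants),
                      x$scaling_constants), collapse = ", "), "\n")
  invisible(x)
}
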