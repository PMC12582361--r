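# Stage-trend linear mixed models, epileptogenicity/SOZ logistic mixed
# models, Bonferroni correction, Cohen's d and the subtraction predictor.

.LMM_COVARS <- c("age_years", "sex", "hemisphere", "is_lesional",
                 "daily_seizures", "n_asm", "surgery_stages")

.drop_constant <- function(df, covars) {
  covars[vapply(covars, function(v) length(unique(df[[v]])) > 1L, TRUE)]
}

.model_result <- function(terms, m, converged, type, resid_q = NULL) {
  structure(list(terms = terms, m_comparisons = m, converged = converged,
                 model_type = type, residual_quantiles = resid_q),
            class = "sevo_model")
}

#' @export
print.sevo_model <- function(x, ...) {
  cat(sprintf("<sevo_model> %s (Bonferroni m = %d, converged = %s)\n",
              x$model_type, x$m_comparisons, x$converged))
  print(x$terms, digits = 4)
  invisible(x)
}

#' Bonferroni adjustment
#' @param p uncorrected p-value(s) in [0, 1].
#' @param m number of comparisons (>= 1).
#' @return min(1, p * m), vectorized.
#' @export
bonferroni_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, p * m)
}

#' Linear mixed model of the normative stage trend
#'
#' Fits biomarker value against the ordinal anaesthetic-stage code
#' (control = 0, sevoflurane minutes 1..9) with the patient-level
#' covariates as fixed effects and a random intercept per patient
#' (optionally a random stage slope), by REML with Satterthwaite degrees of
#' freedom. Restricted to normative channels. Covariates constant within
#' the fitted subset are dropped. Bonferroni m = 6 by default (three
#' control contrasts times two biomarkers in the study design).
#'
#' @param table biomarker table (see [compute_biomarkers()]); needs columns
#'   `patient_id`, `stage`, `epoch_index`, `biomarker`, `value`, `normative`
#'   and the covariates.
#' @param biomarker which biomarker to model (e.g. "MI", "HFO_EC").
#' @param control reference stage, "Iso" or "SWS"; with "SWS" the fit is
#'   restricted to two-stage patients.
#' @param m_comparisons Bonferroni m (default 6).
#' @param random_slope also fit a per-patient random stage slope.
#' @return a `sevo_model`; `$terms` has one row per fixed effect with
#'   estimate, SE, df, t, p and Bonferroni-corrected p; residual quantiles
#'   are attached for Q-Q diagnostics.
#' @export
fit_stage_lmm <- function(table, biomarker, control = c("Iso", "SWS"),
                          m_comparisons = 6L, random_slope = FALSE) {
  control <- match.arg(control)
  d <- table[table$biomarker == biomarker & table$normative &
               table$stage %in% c(control, SEV_STAGES), , drop = FALSE]
  if (control == "SWS") d <- d[d$surgery_stages == 2L, , drop = FALSE]
  d <- d[is.finite(d$value), , drop = FALSE]
  if (length(unique(d$patient_id)) < 2L)
    stop("need at least two patients for a mixed model")
  d$stage_code <- stage_code(d$stage, d$epoch_index)
  covars <- .drop_constant(d, .LMM_COVARS)
  rhs <- paste(c(covars, "stage_code"), collapse = " + ")
  re <- if (random_slope) "(1 + stage_code | patient_id)" else "(1 | patient_id)"
  # fit on the standardized response for optimizer conditioning; estimates
  # and SEs are rescaled back (t, df, p are scale-invariant)
  v_scale <- stats::sd(d$value)
  if (!is.finite(v_scale) || v_scale == 0) v_scale <- 1
  d$value_s <- d$value / v_scale
  form <- stats::as.formula(paste("value_s ~", rhs, "+", re))
  fit <- tryCatch(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(optimizer = "bobyqa")),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(.model_result(NULL, m_comparisons, FALSE, "stage_lmm"))
  converged <- .lme4_converged(fit, .covariate_saturation(d, covars))
  co <- as.data.frame(summary(fit)$coefficients)
  terms <- data.frame(term = rownames(co),
                      estimate = co[["Estimate"]] * v_scale,
                      se = co[["Std. Error"]] * v_scale, df = co[["df"]],
                      statistic = co[["t value"]], p = co[["Pr(>|t|)"]],
                      row.names = NULL)
  terms$p_corrected <- if (converged) bonferroni_adjust(terms$p, m_comparisons)
                       else NA_real_
  rq <- stats::quantile(stats::residuals(fit) * v_scale,
                        probs = seq(0.01, 0.99, 0.01))
  .model_result(terms, m_comparisons, converged, "stage_lmm", rq)
}

#' Binary logistic mixed model of epileptogenic / SOZ status
#'
#' At a given anaesthetic stage, models channel status (epileptogenic =
#' resected in a seizure-free patient, or SOZ) against the biomarker value
#' plus the patient-level covariates, with a random intercept per patient.
#' `stage` may be a minute label ("Sev3_2") or a bare stage name, in which
#' case per-channel values are averaged over the stage's analysis epochs.
#' Bonferroni m = 40 by default (2 controls x 2 biomarkers x 10 stages).
#'
#' @inheritParams fit_stage_lmm
#' @param stage stage(s) or stage-minute(s) to analyse; several labels pool
#'   their epochs.
#' @param label "epileptogenic" or "soz".
#' @param m_comparisons Bonferroni m (default 40).
#' @return a `sevo_model`; the biomarker row carries `or = exp(estimate)`.
#' @export
fit_epi_glmm <- function(table, biomarker, stage,
                         label = c("epileptogenic", "soz"),
                         m_comparisons = 40L) {
  label <- match.arg(label)
  d <- .stage_slice(table, biomarker, stage)
  d$resp <- if (label == "epileptogenic") d$is_resected else d$is_soz
  if (length(unique(d$resp)) < 2L)
    stop("both ", label, " classes must be present")
  agg <- stats::aggregate(value ~ patient_id + channel + resp + age_years +
                            sex + hemisphere + is_lesional + daily_seizures +
                            n_asm + surgery_stages, data = d, FUN = mean)
  covars <- .drop_constant(agg, .LMM_COVARS)
  # fit on the standardized value for conditioning; report per-unit effects
  v_scale <- stats::sd(agg$value)
  if (!is.finite(v_scale) || v_scale == 0) stop("biomarker value is constant")
  agg$value_s <- agg$value / v_scale
  form <- stats::as.formula(paste(
    "resp ~", paste(c(covars, "value_s"), collapse = " + "),
    "+ (1 | patient_id)"))
  warn <- character()
  try_fit <- function(...) withCallingHandlers(
    tryCatch(lme4::glmer(form, data = agg, family = stats::binomial,
                         control = lme4::glmerControl(optimizer = "bobyqa"),
                         ...),
             error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  fit <- try_fit()
  if (inherits(fit, "error")) fit <- try_fit(nAGQ = 0L)   # PIRLS-only fallback
  covariates_dropped <- FALSE
  if (inherits(fit, "error")) {
    # saturated patient-level covariates (few patients) can defeat the fit
    # outright; they are redundant with the patient random intercept, so
    # retry with the biomarker alone and flag the reduction
    form <- stats::as.formula("resp ~ value_s + (1 | patient_id)")
    covariates_dropped <- TRUE
    fit <- try_fit()
    if (inherits(fit, "error")) fit <- try_fit(nAGQ = 0L)
  }
  if (inherits(fit, "error"))
    return(.model_result(NULL, m_comparisons, FALSE, "epi_glmm"))
  converged <- .lme4_converged(fit, .covariate_saturation(agg, covars)) &&
    !any(grepl("failed to converge", warn))
  co <- as.data.frame(summary(fit)$coefficients)
  terms <- data.frame(term = rownames(co), estimate = co[["Estimate"]],
                      se = co[["Std. Error"]], statistic = co[["z value"]],
                      p = co[["Pr(>|z|)"]], row.names = NULL)
  vrow <- terms$term == "value_s"
  terms$term[vrow] <- "value"
  terms$estimate[vrow] <- terms$estimate[vrow] / v_scale
  terms$se[vrow] <- terms$se[vrow] / v_scale
  terms$p_corrected <- bonferroni_adjust(terms$p, m_comparisons)
  terms$or <- exp(terms$estimate)
  out <- .model_result(terms, m_comparisons, converged, "epi_glmm")
  out$covariates_dropped <- covariates_dropped
  out
}

# Singular (zero-variance) random effects are boundary fits. Degenerate /
# singular Hessians are additionally tolerated only when the patient-level
# covariate block is saturated (as many patient-level parameters as
# patients): there the Hessian degeneracy is structural and the
# channel-level terms remain well determined. At study-scale patient
# counts the same messages mark genuine non-convergence.
.lme4_converged <- function(fit, covariate_saturated = FALSE) {
  msgs <- fit@optinfo$conv$lme4$messages
  if (length(msgs) == 0L) return(TRUE)
  pat <- "singular fit|boundary"
  if (covariate_saturated)
    pat <- paste0(pat, "|singular|unable to evaluate scaled gradient|",
                  "degenerate *Hessian")
  all(grepl(pat, msgs, ignore.case = TRUE))
}

# covariates constant within every patient, versus the number of patients
.covariate_saturation <- function(d, covars) {
  pl <- vapply(covars, function(v)
    all(tapply(d[[v]], d$patient_id,
               function(x) length(unique(x)) == 1L)), TRUE)
  sum(pl) + 1L >= length(unique(d$patient_id))
}

# rows of one biomarker at one or more stages / stage-minutes
.stage_slice <- function(table, biomarker, stage) {
  d <- table[table$biomarker == biomarker, , drop = FALSE]
  keep <- rep(FALSE, nrow(d))
  for (st in stage) {
    if (grepl("_", st)) {
      parts <- strsplit(st, "_", fixed = TRUE)[[1L]]
      keep <- keep | (d$stage == parts[1L] &
                        d$epoch_index == as.integer(parts[2L]))
    } else {
      keep <- keep | d$stage == st
    }
  }
  d <- d[keep & is.finite(d$value), , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no rows for ", biomarker, " at stage ",
         paste(stage, collapse = "/"))
  d
}

#' Cohen's d between site classes, per anaesthetic stage
#'
#' For each patient and 1-min epoch the effect size is
#' |mean(class sites) - mean(other sites)| / SD(all sites of that
#' patient-epoch); patient-epochs with a single class are skipped. Values
#' are then averaged over patients and 1-min epochs to one d per stage.
#'
#' @inheritParams fit_epi_glmm
#' @return data.frame with `stage`, `d`, and `n` (patient-epochs
#'   contributing).
#' @export
cohens_d_by_stage <- function(table, biomarker,
                              label = c("epileptogenic", "soz")) {
  label <- match.arg(label)
  d <- table[table$biomarker == biomarker & is.finite(table$value), ,
             drop = FALSE]
  d$cls <- if (label == "epileptogenic") d$is_resected else d$is_soz
  key <- interaction(d$patient_id, d$stage, d$epoch_index, drop = TRUE)
  per <- lapply(split(d, key), function(g) {
    if (length(unique(g$cls)) < 2L) return(NULL)
    data.frame(stage = g$stage[1L],
               d = abs(mean(g$value[g$cls]) - mean(g$value[!g$cls])) /
                 stats::sd(g$value))
  })
  per <- do.call(rbind, per)
  if (is.null(per)) stop("no patient-epoch contains both classes")
  out <- stats::aggregate(d ~ stage, data = per, FUN = mean)
  out$n <- stats::aggregate(d ~ stage, data = per, FUN = length)$d
  out
}

#' Resection-completeness subtraction predictor
#'
#' Per patient: mean biomarker value over resected sites minus mean over
#' retained sites at the given stage (averaged over its epochs). Patients
#' missing either class are excluded with a warning. Higher values indicate
#' more complete resection of high-biomarker tissue; with seizure outcome
#' labels the values feed an ordinary logistic fit.
#'
#' @inheritParams fit_epi_glmm
#' @param outcome optional named logical vector (by patient) of ILAE Class I
#'   seizure freedom; when supplied a logistic `glm` of outcome on the
#'   subtraction value is attached as attribute `outcome_model`.
#' @return data.frame with `patient_id`, `subtraction`.
#' @export
subtraction_predictor <- function(table, biomarker, stage, outcome = NULL) {
  d <- .stage_slice(table, biomarker, stage)
  out <- lapply(split(d, d$patient_id), function(g) {
    if (!any(g$is_resected) || all(g$is_resected)) {
      warning("patient ", g$patient_id[1L],
              " lacks resected or retained sites; excluded")
      return(NULL)
    }
    data.frame(patient_id = g$patient_id[1L],
               subtraction = mean(g$value[g$is_resected]) -
                 mean(g$value[!g$is_resected]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!is.null(outcome)) {
    res$outcome <- outcome[res$patient_id]
    attr(res, "outcome_model") <-
      stats::glm(outcome ~ subtraction, data = res, family = stats::binomial)
  }
  res
}

#' Log-transformed biomarker table
#'
#' value -> log(value + eps), with eps = (smallest positive value) / 2 per
#' biomarker, applied only when that biomarker contains zeros. Monotone, so
#' ranks are preserved. A biomarker that is identically zero is an error.
#'
#' @param table biomarker table.
#' @return the table with transformed values.
#' @export
log_variant <- function(table) {
  out <- table
  for (bm in unique(table$biomarker)) {
    sel <- table$biomarker == bm & is.finite(table$value)
    v <- table$value[sel]
    if (any(v < 0)) stop("negative ", bm, " values cannot be log-transformed")
    if (all(v == 0)) stop("biomarker ", bm, " is identically zero")
    eps <- if (any(v == 0)) min(v[v > 0]) / 2 else 0
    out$value[sel] <- log(v + eps)
  }
  out
}
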