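#' Covariate model specifications for the trial's model ladder
#'
#' The five nested adjustment models used throughout the analyses:
#' model 1 adjusts for sex, age at randomization (restricted cubic spline,
#' 3 knots) and recruitment cohort; model 2 adds BMI (spline), smoking status
#' and aspirin use; model 3 adds the alternative Healthy Eating Index
#' (spline), family history and hypertension history; model 4 is model 2 plus
#' randomized assignment; model 5 is model 2 plus aHEI.
#'
#' @param model_id integer 1..5, or 0 for an unadjusted (exposure-only) model.
#' @param exposure_contrast which exposure definition the model will be fitted
#'   under: `"itt"`, `"pp"` or `"biomarker"` (metadata used for labelling).
#' @return object of class `model_spec`: named list of covariate encodings
#'   (`"rcs3"`, `"categorical"`, `"binary"`).
#' @export
model_spec <- function(model_id = 2, exposure_contrast = c("biomarker", "itt", "pp")) {
  exposure_contrast <- match.arg(exposure_contrast)
  if (!model_id %in% 0:5) stop("`model_id` must be one of 0, 1, 2, 3, 4, 5")
  m1 <- list(sex = "categorical", age_at_randomization = "rcs3", cohort = "categorical")
  m2 <- c(m1, list(bmi = "rcs3", smoking = "categorical", aspirin_use = "binary"))
  covs <- switch(as.character(model_id),
    "0" = list(),
    "1" = m1,
    "2" = m2,
    "3" = c(m2, list(ahei = "rcs3", family_history = "binary",
                     hypertension_history = "binary")),
    "4" = c(m2, list(arm = "categorical")),
    "5" = c(m2, list(ahei = "rcs3"))
  )
  structure(list(model_id = model_id, covariates = covs,
                 exposure_contrast = exposure_contrast),
            class = "model_spec")
}

# expand covariates per the spec's encodings into numeric/factor columns;
# spline knots are taken from `knots` when supplied (reference-profile
# evaluation) or placed at the data's 0.1/0.5/0.9 quantiles and recorded
encode_covariates <- function(data, spec, knots = NULL) {
  out <- list()
  used_knots <- list()
  for (nm in names(spec$covariates)) {
    enc <- spec$covariates[[nm]]
    if (!nm %in% names(data)) stop(sprintf("covariate `%s` missing from data", nm))
    v <- data[[nm]]
    if (enc == "rcs3") {
      b <- rcs3_basis(v, knots = knots[[nm]])
      used_knots[[nm]] <- attr(b, "knots")
      out[[paste0(nm, "_lin")]] <- b[, "lin"]
      if (ncol(b) > 1) out[[paste0(nm, "_nl")]] <- b[, "nl"]
    } else if (enc == "categorical") {
      out[[nm]] <- if (is.factor(v)) v else factor(v)
    } else {
      out[[nm]] <- as.numeric(v)
    }
  }
  list(frame = if (length(out)) as.data.frame(out, stringsAsFactors = FALSE) else NULL,
       knots = used_knots)
}

#' Fit a Cox proportional-hazards model for one exposure contrast
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default) for a
#' binary exposure plus the covariates of a [model_spec()], returning the
#' exposure hazard ratio with its Wald 95% interval and a Schoenfeld-residual
#' proportional-hazards test (the `cox.zph` construction, identity time
#' transform by default).
#'
#' @param data a survival dataset: data.frame with columns `time`, `event`,
#'   `exposure` (0/1 or logical) and the model's covariates (see
#'   [build_survival_dataset()]).
#' @param spec a [model_spec()]; `NULL` fits the exposure alone.
#' @param ties tie-handling method passed to [survival::coxph()].
#' @param ph_transform time transform for the proportional-hazards test.
#' @return object of class `cox_result`.
#' @export
fit_cox <- function(data, spec = NULL, ties = "efron", ph_transform = "identity") {
  if (!all(c("time", "event", "exposure") %in% names(data)))
    stop("`data` must have columns time, event, exposure")
  if (any(data$time <= 0)) stop("all times must be > 0")
  exposure <- as.integer(as.logical(data$exposure))
  ev <- as.logical(data$event)
  if (length(unique(exposure)) < 2)
    stop_not_estimable("only one exposure group present")
  if (any(tapply(ev, exposure, sum) < 1))
    stop_not_estimable("no events in one exposure group")

  if (is.null(spec)) spec <- model_spec(0)
  enc <- encode_covariates(data, spec)
  df <- data.frame(time = data$time, event = ev, exposure = exposure)
  if (!is.null(enc$frame)) df <- cbind(df, enc$frame)
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~ exposure",
    if (ncol(df) > 3) paste("+", paste(names(df)[-(1:3)], collapse = " + ")) else ""
  ))
  # convergence chatter about covariate terms is muffled here; the exposure
  # coefficient has its own stability check below
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties, x = TRUE),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  co <- summary(fit)
  b <- co$coefficients["exposure", "coef"]
  se <- co$coefficients["exposure", "se(coef)"]
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15)
    stop_not_estimable("exposure coefficient unstable (possible separation)")

  ph <- tryCatch({
    z <- survival::cox.zph(fit, transform = ph_transform)
    z$table["exposure", , drop = TRUE]
  }, error = function(e) NULL)

  structure(list(
    endpoint = attr(data, "endpoint") %||% NA_character_,
    contrast = attr(data, "contrast") %||% spec$exposure_contrast,
    model_id = spec$model_id,
    hr = exp(b), ci_low = exp(b - 1.959964 * se), ci_high = exp(b + 1.959964 * se),
    log_hr = b, log_hr_se = se,
    n_used = fit$n, n_events = fit$nevent,
    ph_test = ph,
    n_imputations_pooled = 1L,
    knots = enc$knots,
    fit = fit
  ), class = "cox_result")
}

stop_not_estimable <- function(msg) {
  stop(structure(class = c("flavatrial_not_estimable", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat(sprintf("Cox model (%s contrast, model %s%s): HR %.*f (95%% CI %.*f-%.*f)\n",
              x$contrast, x$model_id,
              if (!is.na(x$endpoint)) paste0(", ", x$endpoint) else "",
              digits, x$hr, digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  n = %d, events = %d, log-HR %.4f (SE %.4f)",
              x$n_used, x$n_events, x$log_hr, x$log_hr_se))
  if (x$n_imputations_pooled > 1)
    cat(sprintf(", pooled over %d imputations", x$n_imputations_pooled))
  cat("\n")
  if (!is.null(x$ph_test))
    cat(sprintf("  PH test (exposure): chisq = %.3f, p = %.3f\n",
                x$ph_test[["chisq"]], x$ph_test[["p"]]))
  invisible(x)
}

#' Per-protocol censoring times from adherence self-reports
#'
#' The per-protocol rule censors each participant at the earliest self-report
#' of missing more than 8 pills per month, being unsure how many were missed,
#' or outside supplement use. Participants who never file such a report keep
#' their full follow-up.
#'
#' @param participants participant table (column `id`).
#' @param self_reports self-report table (`participant_id`, `report_date` in
#'   days since randomization, `status`).
#' @param events optional event table; flagged reports dated after a recorded
#'   event are counted in the `n_reports_after_event` attribute (the censoring
#'   time itself is unaffected: censoring after the event leaves the event in
#'   place).
#' @return data.frame `participant_id`, `censor_time` (years; `Inf` when never
#'   flagged).
#' @export
pp_censor <- function(participants, self_reports, events = NULL) {
  flagged <- self_reports[self_reports$status %in% selfreport_levels()[2:4], , drop = FALSE]
  first <- tapply(flagged$report_date, flagged$participant_id, min)
  idx <- match(as.character(participants$id), names(first))
  ct <- as.numeric(first[idx]) / 365.25
  ct[is.na(ct)] <- Inf
  out <- data.frame(participant_id = participants$id, censor_time = ct)
  if (!is.null(events)) {
    death <- events[events$event, c("participant_id", "time")]
    first_ev <- tapply(death$time, death$participant_id, min)
    ev_idx <- match(as.character(participants$id), names(first_ev))
    attr(out, "n_reports_after_event") <-
      sum(is.finite(ct) & !is.na(ev_idx) & ct > as.numeric(first_ev[ev_idx]))
  }
  out
}

#' Assemble the per-participant survival dataset for one endpoint and contrast
#'
#' `itt` uses randomized arm on all participants; `pp` uses randomized arm
#' with follow-up truncated at the per-protocol censoring time; `biomarker`
#' uses the biomarker-active vs biomarker-control groups, dropping excluded
#' and unclassifiable participants.
#'
#' @param cohort a `flavanol_cohort` (or any list with `participants`,
#'   `events`, and `self_reports` when `contrast = "pp"`).
#' @param endpoint one of `"total_cvd"`, `"cvd_mortality"`,
#'   `"all_cause_mortality"`, `"major_cvd"`.
#' @param contrast `"itt"`, `"pp"` or `"biomarker"`.
#' @param classifications [classify_participants()] output (required for the
#'   biomarker contrast).
#' @return data.frame of class `survival_dataset` with attributes `endpoint`
#'   and `contrast`.
#' @export
build_survival_dataset <- function(cohort, endpoint = "total_cvd",
                                   contrast = c("itt", "pp", "biomarker"),
                                   classifications = NULL) {
  contrast <- match.arg(contrast)
  endpoint <- match.arg(endpoint, endpoint_levels())
  p <- cohort$participants
  ev <- cohort$events
  ev <- ev[ev$endpoint == endpoint, , drop = FALSE]
  idx <- match(p$id, ev$participant_id)
  if (any(is.na(idx))) stop("missing event rows for some participants")
  d <- p
  d$time <- ev$time[idx]
  d$event <- ev$event[idx]

  if (contrast == "biomarker") {
    if (is.null(classifications))
      stop("`classifications` is required for the biomarker contrast")
    g <- classifications$group[match(p$id, classifications$participant_id)]
    keep <- !is.na(g) & g != "excluded"
    d <- d[keep, , drop = FALSE]
    d$exposure <- as.integer(g[keep] == "biomarker_active")
  } else {
    d$exposure <- as.integer(d$arm == "intervention")
    if (contrast == "pp") {
      ct <- pp_censor(p, cohort$self_reports)
      cti <- ct$censor_time[match(d$id, ct$participant_id)]
      d$event <- d$event & d$time <= cti
      d$time <- pmin(d$time, cti)
    }
  }
  structure(d, endpoint = endpoint, contrast = contrast,
            class = c("survival_dataset", "data.frame"))
}

#' Fit all requested endpoint-by-contrast-by-model Cox analyses
#'
#' Runs the intention-to-treat, per-protocol and biomarker-based contrasts for
#' each endpoint under each requested adjustment model and collects the hazard
#' ratios into one tidy table. Cells whose exposure groups are empty or
#' event-free are flagged not-estimable rather than dropped.
#'
#' @param cohort a `flavanol_cohort`.
#' @param classifications [classify_participants()] output (needed when
#'   `"biomarker"` is among the contrasts).
#' @param contrasts,models,endpoints which cells to fit.
#' @return data.frame with one row per cell (`endpoint`, `contrast`,
#'   `model_id`, `hr`, `ci_low`, `ci_high`, `log_hr`, `log_hr_se`, `n`,
#'   `events`, `not_estimable`) and attribute `"results"` holding the
#'   underlying `cox_result` objects.
#' @export
run_contrasts <- function(cohort, classifications = NULL,
                          contrasts = c("itt", "pp", "biomarker"),
                          models = 2, endpoints = endpoint_levels()) {
  rows <- list()
  fits <- list()
  for (ep in endpoints) for (ctr in contrasts) for (mid in models) {
    key <- paste(ep, ctr, mid, sep = ".")
    res <- tryCatch({
      d <- build_survival_dataset(cohort, ep, ctr, classifications)
      fit_cox(d, model_spec(mid, exposure_contrast =
                              if (ctr == "biomarker") "biomarker" else ctr))
    }, flavatrial_not_estimable = function(e) e)
    ne <- inherits(res, "flavatrial_not_estimable")
    if (!ne) fits[[key]] <- res
    rows[[key]] <- data.frame(
      endpoint = ep, contrast = ctr, model_id = mid,
      hr = if (ne) NA_real_ else res$hr,
      ci_low = if (ne) NA_real_ else res$ci_low,
      ci_high = if (ne) NA_real_ else res$ci_high,
      log_hr = if (ne) NA_real_ else res$log_hr,
      log_hr_se = if (ne) NA_real_ else res$log_hr_se,
      n = if (ne) NA_integer_ else res$n_used,
      events = if (ne) NA_integer_ else res$n_events,
      not_estimable = ne,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- fits
  out
}
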