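#' Parameters for the synthetic trial-cohort generator
#'
#' Bundles the generative assumptions of the synthetic randomized nutrition
#' trial: background-diet contamination, pill adherence, the dose--response
#' model linking actual flavanol intake to urinary biomarker concentrations,
#' self-report misreporting, and per-endpoint event hazards. Defaults encode
#' the structure of a large cocoa-flavanol supplementation trial: roughly 20%
#' of participants obtain an intervention-sized dose (>= 500 mg/d) from their
#' habitual diet alone, about 5% consume essentially none (urine below the
#' limit of quantification), about two thirds of the intervention arm actually
#' take their pills, and spot urine at follow-up exists for only ~32% of the
#' cohort.
#'
#' @param n_total number of randomized participants.
#' @param p_arm probability of assignment to the flavanol intervention arm.
#' @param p_background_high probability the habitual diet supplies at least
#'   `dose_ref` mg/d of flavanols.
#' @param p_background_zero probability of negligible intake (urine below the
#'   limit of quantification).
#' @param p_adherent probability that a participant actually takes the study
#'   pills (drawn for both arms; only consequential for exposure in the
#'   intervention arm).
#' @param p_followup_sample probability that any follow-up urine sample exists.
#' @param dose_ref reference daily dose in mg defining "exposed" (default 500).
#' @param dose_response per-biomarker `(intercept, slope, sd)` of the linear
#'   model for log2 urine concentration (micromolar) as a function of daily
#'   dose in mg. Defaults are calibrated so that the lower 95% prediction bound
#'   at 500 mg/d sits at 18.2 uM (gVLM) and 7.8 uM (SREM).
#' @param true_log_hr named per-endpoint log hazard ratio caused by actual
#'   exposure at or above `dose_ref`.
#' @param baseline_hazard named per-endpoint event rate (events per
#'   person-year) in unexposed participants.
#' @param followup_years administrative censoring time in years.
#' @param p_selfreport_nonadherent_given_adherent probability an adherent
#'   participant ever files a non-adherent self-report (false flag).
#' @param p_selfreport_adherent_given_nonadherent probability a non-adherent
#'   participant never files a non-adherent self-report (misreport).
#' @param loq per-biomarker limit of quantification in micromolar.
#' @param background_moderate_meanlog,background_moderate_sdlog lognormal
#'   parameters for the moderate background dose (mg/d), truncated below
#'   `dose_ref`.
#' @param background_high_range uniform range (mg/d) for high background doses.
#' @param continuous_dose if `TRUE`, draw background intake from a single
#'   continuous lognormal distribution instead of the three-component
#'   (zero / moderate / high) mixture.
#' @param seed master RNG seed; every stochastic sub-table derives its own
#'   stage seed from it.
#'
#' @return an object of class `cohort_params` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_params <- function(n_total = 6509,
                          p_arm = 0.5,
                          p_background_high = 0.20,
                          p_background_zero = 0.05,
                          p_adherent = 0.67,
                          p_followup_sample = 0.315,
                          dose_ref = 500,
                          dose_response = default_dose_response(),
                          true_log_hr = c(total_cvd = log(0.65),
                                          cvd_mortality = log(0.44),
                                          all_cause_mortality = log(0.54),
                                          major_cvd = log(0.48)),
                          baseline_hazard = c(total_cvd = 0.0105,
                                              cvd_mortality = 0.0018,
                                              all_cause_mortality = 0.008,
                                              major_cvd = 0.0068),
                          followup_years = 3.6,
                          p_selfreport_nonadherent_given_adherent = 0.02,
                          p_selfreport_adherent_given_nonadherent = 0.59,
                          loq = c(gvlm = 0.5, srem = 0.25),
                          background_moderate_meanlog = log(60),
                          background_moderate_sdlog = 0.6,
                          background_high_range = c(500, 900),
                          continuous_dose = FALSE,
                          seed = 1L) {
  p <- list(
    n_total = n_total, p_arm = p_arm,
    p_background_high = p_background_high,
    p_background_zero = p_background_zero,
    p_adherent = p_adherent, p_followup_sample = p_followup_sample,
    dose_ref = dose_ref, dose_response = dose_response,
    true_log_hr = true_log_hr, baseline_hazard = baseline_hazard,
    followup_years = followup_years,
    p_selfreport_nonadherent_given_adherent = p_selfreport_nonadherent_given_adherent,
    p_selfreport_adherent_given_nonadherent = p_selfreport_adherent_given_nonadherent,
    loq = loq,
    background_moderate_meanlog = background_moderate_meanlog,
    background_moderate_sdlog = background_moderate_sdlog,
    background_high_range = background_high_range,
    continuous_dose = isTRUE(continuous_dose),
    seed = seed
  )
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

endpoint_levels <- function() {
  c("total_cvd", "cvd_mortality", "all_cause_mortality", "major_cvd")
}

#' Default dose--response truth used by the generator
#'
#' Per-biomarker intercept, slope and residual sd of log2 urine concentration
#' (micromolar) against daily flavanol dose (mg). Slopes are chosen so the
#' lower two-sided 95% bound of the concentration distribution at the 500 mg/d
#' reference dose equals the standard classification thresholds (18.2 uM for
#' gVLM, 7.8 uM for SREM).
#'
#' @return data.frame with columns `biomarker`, `intercept`, `slope`, `sd`.
#' @export
default_dose_response <- function() {
  sd <- 0.8
  z <- stats::qnorm(0.975)
  data.frame(
    biomarker = c("gvlm", "srem"),
    intercept = c(1, 0),
    slope = c((log2(18.2) + z * sd - 1) / 500, (log2(7.8) + z * sd - 0) / 500),
    sd = c(sd, sd),
    stringsAsFactors = FALSE
  )
}

validate_cohort_params <- function(p) {
  for (f in c("p_arm", "p_background_high", "p_background_zero", "p_adherent",
              "p_followup_sample", "p_selfreport_nonadherent_given_adherent",
              "p_selfreport_adherent_given_nonadherent"))
    check_prob(p[[f]], f)
  if (p$p_background_high + p$p_background_zero > 1)
    stop_field("p_background_high", "p_background_high + p_background_zero must not exceed 1")
  if (!is.numeric(p$n_total) || length(p$n_total) != 1L || !is.finite(p$n_total) ||
      p$n_total < 1)
    stop_field("n_total", "must be a single positive count")
  check_pos(p$dose_ref, "dose_ref")
  check_pos(p$followup_years, "followup_years")
  dr <- p$dose_response
  if (!is.data.frame(dr) ||
      !all(c("biomarker", "intercept", "slope", "sd") %in% names(dr)) ||
      !all(c("gvlm", "srem") %in% dr$biomarker))
    stop_field("dose_response", "must be a data.frame with rows for gvlm and srem")
  if (any(!is.finite(dr$intercept)) || any(!is.finite(dr$slope)))
    stop_field("dose_response", "coefficients must be finite")
  check_pos(dr$sd, "dose_response$sd")
  ep <- endpoint_levels()
  if (!all(ep %in% names(p$true_log_hr)))
    stop_field("true_log_hr", "must be named for every endpoint")
  if (any(!is.finite(p$true_log_hr)))
    stop_field("true_log_hr", "must be finite")
  if (!all(ep %in% names(p$baseline_hazard)))
    stop_field("baseline_hazard", "must be named for every endpoint")
  check_pos(unname(p$baseline_hazard), "baseline_hazard")
  check_pos(unname(p$loq), "loq")
  if (!is.numeric(p$seed) || length(p$seed) != 1L || !is.finite(p$seed))
    stop_field("seed", "must be a single finite number")
  invisible(p)
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic trial cohort parameters\n")
  cat(sprintf("  n_total: %d, intervention p: %.2f\n", as.integer(x$n_total), x$p_arm))
  cat(sprintf("  background: %.0f%% high, %.0f%% zero; adherence: %.0f%%; follow-up sample: %.0f%%\n",
              100 * x$p_background_high, 100 * x$p_background_zero,
              100 * x$p_adherent, 100 * x$p_followup_sample))
  cat(sprintf("  reference dose: %g mg/d, follow-up: %g y, seed: %s\n",
              x$dose_ref, x$followup_years, format(x$seed)))
  invisible(x)
}
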