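#' Fit a log2 dose--response model to calibration records
#'
#' Ordinary least squares of log2(urine concentration, micromolar) on the
#' (optionally log2-transformed) daily flavanol dose, as used to calibrate
#' intake thresholds from a dose-escalation study. Records with non-positive
#' concentration cannot be log-transformed; they are excluded from the fit
#' with a warning listing their row numbers and counted in the result.
#'
#' @param records data.frame with columns `dose` (mg/d, > 0), `concentration`
#'   (micromolar) and optionally `biomarker`.
#' @param dose_transform `"identity"` (default: concentration is
#'   log-transformed, dose is not) or `"log2"`.
#' @return object of class `dose_response_fit`: coefficients on the log2 scale,
#'   residual sd (n - 2 denominator), coefficient covariance, dose range, and
#'   counts of used/rejected records.
#' @examples
#' rec <- data.frame(dose = c(100, 200, 400), concentration = 2^(1 + 0.004 * c(100, 200, 400)))
#' fit_dose_response(rec)
#' @export
fit_dose_response <- function(records, dose_transform = c("identity", "log2")) {
  dose_transform <- match.arg(dose_transform)
  if (!is.data.frame(records) || !all(c("dose", "concentration") %in% names(records)))
    stop("`records` must be a data.frame with columns `dose` and `concentration`")
  if (any(!is.finite(records$dose)) || any(records$dose <= 0))
    stop("all calibration doses must be finite and > 0")
  bad <- which(!is.finite(records$concentration) | records$concentration <= 0)
  if (length(bad)) {
    warning(sprintf("excluding %d record(s) with non-positive concentration (rows: %s)",
                    length(bad), paste(bad, collapse = ", ")))
    records <- records[-bad, , drop = FALSE]
  }
  if (nrow(records) < 3)
    stop("need at least 3 calibration records with positive concentration")
  x <- if (dose_transform == "log2") log2(records$dose) else records$dose
  if (length(unique(x)) < 2)
    stop("degenerate design: calibration records must span at least 2 distinct doses")
  y <- log2(records$concentration)
  fit <- stats::lm(y ~ x)
  # residual sd and coefficient covariance computed directly (summary.lm
  # complains on exact-fit data, which is a legitimate input here)
  n <- nrow(records)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  X <- cbind(1, x)
  biomarker <- if ("biomarker" %in% names(records) &&
                   length(unique(records$biomarker)) == 1L)
    as.character(records$biomarker[1]) else NA_character_
  structure(
    list(
      biomarker = biomarker,
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      residual_sd = sigma,
      n = n,
      n_rejected = length(bad),
      design_covariance = sigma^2 * solve(crossprod(X)),
      dose_transform = dose_transform,
      dose_range = range(records$dose)
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response calibration fit (%s)\n",
              if (is.na(x$biomarker)) "biomarker unspecified" else x$biomarker))
  cat(sprintf("  log2(conc) = %.4f + %.6f * %s(dose),  residual sd %.4f, n = %d\n",
              x$intercept, x$slope,
              if (x$dose_transform == "log2") "log2" else "", x$residual_sd, x$n))
  if (x$n_rejected > 0) cat(sprintf("  (%d non-positive record(s) excluded)\n", x$n_rejected))
  invisible(x)
}

#' Derive an intake-classification threshold from a calibration fit
#'
#' Returns the lower bound of a two-sided interval for log2 concentration at
#' the target dose, back-transformed to micromolar. With
#' `interval_kind = "mean_ci"` the interval is the confidence interval for the
#' expected (mean) concentration; with `"prediction"` (default) it is the
#' prediction interval for a new individual, which additionally carries the
#' residual (inter-individual) variance and therefore gives a lower, more
#' conservative threshold that reduces false-negative classification of truly
#' exposed individuals. Student-t quantiles with n - 2 degrees of freedom are
#' used throughout.
#'
#' @param fit a [fit_dose_response()] result.
#' @param dose target daily dose in mg (default 500).
#' @param level two-sided interval level in (0, 1), default 0.95.
#' @param interval_kind `"prediction"` or `"mean_ci"`.
#' @return threshold in micromolar, with attribute `log2_lower` holding the
#'   untransformed lower bound.
#' @export
derive_threshold <- function(fit, dose = 500, level = 0.95,
                             interval_kind = c("prediction", "mean_ci")) {
  interval_kind <- match.arg(interval_kind)
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be a single value strictly inside (0, 1)")
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose <= 0)
    stop("`dose` must be a single positive value")
  if (dose < fit$dose_range[1] || dose > fit$dose_range[2])
    warning(sprintf("dose %g mg is outside the calibration range [%g, %g]: extrapolating",
                    dose, fit$dose_range[1], fit$dose_range[2]))
  x0 <- if (fit$dose_transform == "log2") log2(dose) else dose
  v <- c(1, x0)
  se2_mean <- drop(t(v) %*% fit$design_covariance %*% v)
  se <- sqrt(se2_mean + if (interval_kind == "prediction") fit$residual_sd^2 else 0)
  tq <- stats::qt(1 - (1 - level) / 2, df = fit$n - 2)
  lower <- fit$intercept + fit$slope * x0 - tq * se
  structure(2^lower, log2_lower = lower)
}

#' Standard threshold profile for the cocoa-flavanol biomarker analysis
#'
#' The documented default thresholds of 18.2 uM (gVLM) and 7.8 uM (SREM),
#' defined as the bottom 95% interval limit of the expected concentration after
#' a 500 mg flavanol intake in the original dose-escalation calibration (whose
#' raw data are not distributed with this package).
#'
#' @return a [threshold_pair()].
#' @export
cosmos_thresholds <- function() {
  threshold_pair(18.2, 7.8, level = 0.95, interval_kind = "prediction")
}

#' Construct a validated pair of classification thresholds
#'
#' @param t_gvlm,t_srem thresholds in micromolar, both > 0.
#' @param level interval level used to derive them (metadata).
#' @param interval_kind `"prediction"` or `"mean_ci"` (metadata).
#' @return object of class `threshold_pair`.
#' @export
threshold_pair <- function(t_gvlm, t_srem, level = 0.95,
                           interval_kind = c("prediction", "mean_ci")) {
  interval_kind <- match.arg(interval_kind)
  check_pos(t_gvlm, "t_gvlm")
  check_pos(t_srem, "t_srem")
  structure(list(t_gvlm = as.numeric(t_gvlm), t_srem = as.numeric(t_srem),
                 level = level, interval_kind = interval_kind),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("Biomarker thresholds: gVLM >= %.3g uM | SREM >= %.3g uM (%s, level %.2f)\n",
              x$t_gvlm, x$t_srem, x$interval_kind, x$level))
  invisible(x)
}

#' Simulate calibration records from a known dose--response truth
#'
#' Draws dose-escalation records with log2-normal concentration noise around a
#' linear dose--response, for testing and demonstrating threshold derivation.
#'
#' @param n number of records.
#' @param intercept,slope,sd truth on the log2-micromolar scale (defaults:
#'   the generator's gVLM truth).
#' @param doses dose levels (mg) cycled over the n records.
#' @param biomarker label attached to the records.
#' @param seed RNG seed.
#' @return data.frame of calibration records.
#' @export
simulate_calibration <- function(n = 40, intercept = NULL, slope = NULL, sd = NULL,
                                 doses = c(100, 200, 300, 400, 500, 750, 1000),
                                 biomarker = "gvlm", seed = 1L) {
  dr <- default_dose_response()
  row <- dr[dr$biomarker == biomarker, ]
  if (nrow(row) == 0) row <- dr[1, ]
  intercept <- intercept %||% row$intercept
  slope <- slope %||% row$slope
  sd <- sd %||% row$sd
  set.seed(stage_seed(seed, "calibration"))
  dose <- rep_len(doses, n)
  data.frame(
    dose = dose,
    concentration = 2^(intercept + slope * dose + stats::rnorm(n, 0, sd)),
    biomarker = biomarker,
    stringsAsFactors = FALSE
  )
}
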