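#' Generate a synthetic randomized nutrition trial cohort
#'
#' Draws a full synthetic trial: participant covariates with latent background
#' intake and pill adherence, spot-urine biomarker samples at baseline and
#' follow-up generated from the dose--response model at each participant's
#' *actual* current flavanol exposure, six-monthly adherence self-reports with
#' misreporting, and per-endpoint exponential event times whose hazard is
#' multiplied by `exp(true_log_hr)` if and only if actual exposure reaches the
#' reference dose. Death censors the other endpoints.
#'
#' Latent columns (`true_background`, `true_background_dose`, `true_adherent`,
#' `true_exposed`) exist for validation oracles only; no analysis function in
#' this package consumes them.
#'
#' @param params a [cohort_params()] object.
#' @return an object of class `flavanol_cohort`: a list with data.frames
#'   `participants`, `urine_samples`, `self_reports`, `events`, and
#'   `calibration_truth` (the generator's dose--response coefficients).
#' @examples
#' coh <- generate_cohort(cohort_params(n_total = 500, seed = 7))
#' head(coh$participants)
#' @export
generate_cohort <- function(params = cohort_params()) {
  validate_cohort_params(params)
  participants <- gen_participants(params)
  urine <- gen_urine(params, participants)
  reports <- gen_selfreports(params, participants)
  events <- gen_events(params, participants)
  structure(
    list(participants = participants, urine_samples = urine,
         self_reports = reports, events = events,
         calibration_truth = params$dose_response,
         params = params),
    class = "flavanol_cohort"
  )
}

#' @export
print.flavanol_cohort <- function(x, ...) {
  p <- x$participants
  cat(sprintf("Synthetic trial cohort: %d participants (%d placebo / %d intervention)\n",
              nrow(p), sum(p$arm == "placebo"), sum(p$arm == "intervention")))
  cat(sprintf("  urine samples: %d (%d baseline, %d follow-up)\n",
              nrow(x$urine_samples), sum(x$urine_samples$visit == "baseline"),
              sum(x$urine_samples$visit != "baseline")))
  cat(sprintf("  self-reports: %d rows; events: %d rows over %d endpoints\n",
              nrow(x$self_reports), nrow(x$events),
              length(unique(x$events$endpoint))))
  invisible(x)
}

gen_participants <- function(params) {
  set.seed(stage_seed(params$seed, "participants"))
  n <- as.integer(params$n_total)
  arm <- factor(ifelse(stats::runif(n) < params$p_arm, "intervention", "placebo"),
                levels = c("placebo", "intervention"))
  sex <- factor(ifelse(stats::runif(n) < 0.59, "female", "male"),
                levels = c("male", "female"))
  cohort <- factor(ifelse(sex == "female" & stats::runif(n) < 0.45, "WHI", "other"),
                   levels = c("other", "WHI"))
  age <- ifelse(sex == "female", 65, 60) + stats::rgamma(n, shape = 2, scale = 3.5)
  age <- pmin(age, 97)
  bmi <- pmax(stats::rnorm(n, 27, 4.5), 16)
  smoking <- factor(sample(c("never", "ever", "current"), n, replace = TRUE,
                           prob = c(0.55, 0.40, 0.05)),
                    levels = c("never", "ever", "current"))
  aspirin_use <- stats::runif(n) < 0.45
  ahei <- stats::rnorm(n, 55, 10)
  hypertension_history <- stats::runif(n) < 0.55
  family_history <- stats::runif(n) < 0.45

  if (params$continuous_dose) {
    dose <- stats::rlnorm(n, meanlog = log(100), sdlog = 1.1)
    background <- cut(dose, c(-Inf, min(params$loq) * 10, params$dose_ref, Inf),
                      labels = c("zero", "moderate", "high"))
    dose[background == "zero"] <- 0
  } else {
    u <- stats::runif(n)
    background <- factor(
      ifelse(u < params$p_background_high, "high",
             ifelse(u > 1 - params$p_background_zero, "zero", "moderate")),
      levels = c("zero", "moderate", "high")
    )
    dose <- numeric(n)
    nh <- sum(background == "high")
    dose[background == "high"] <-
      stats::runif(nh, params$background_high_range[1], params$background_high_range[2])
    nm <- sum(background == "moderate")
    dose[background == "moderate"] <- pmin(
      stats::rlnorm(nm, params$background_moderate_meanlog, params$background_moderate_sdlog),
      params$dose_ref - 1
    )
  }

  true_adherent <- stats::runif(n) < params$p_adherent
  supplement <- ifelse(arm == "intervention" & true_adherent, params$dose_ref, 0)
  true_exposed <- (dose + supplement) >= params$dose_ref

  data.frame(
    id = seq_len(n), arm = arm, age_at_randomization = age, sex = sex,
    bmi = bmi, smoking = smoking, aspirin_use = aspirin_use, cohort = cohort,
    ahei = ahei, hypertension_history = hypertension_history,
    family_history = family_history,
    true_background = background, true_background_dose = dose,
    true_adherent = true_adherent, true_exposed = true_exposed,
    stringsAsFactors = FALSE
  )
}

# draw one biomarker concentration vector at the given actual daily doses;
# dose 0 means negligible intake: the stored value is a sub-LOQ draw, flagged
draw_concentration <- function(dose, coefs, loq) {
  n <- length(dose)
  conc <- 2^(coefs["intercept"] + coefs["slope"] * dose +
               stats::rnorm(n, 0, coefs["sd"]))
  zero <- dose <= 0
  conc[zero] <- loq * stats::runif(sum(zero), 0.05, 0.95)
  below <- conc < loq
  list(conc = conc, below_loq = below)
}

gen_urine <- function(params, participants) {
  set.seed(stage_seed(params$seed, "urine"))
  n <- nrow(participants)
  dr <- params$dose_response
  cg <- unlist(dr[dr$biomarker == "gvlm", c("intercept", "slope", "sd")])
  cs <- unlist(dr[dr$biomarker == "srem", c("intercept", "slope", "sd")])

  base_dose <- participants$true_background_dose
  fu_dose <- base_dose +
    ifelse(participants$arm == "intervention" & participants$true_adherent,
           params$dose_ref, 0)

  has_fu <- stats::runif(n) < params$p_followup_sample
  n_visits <- 1L + stats::rbinom(n, 2L, 0.35)
  n_visits[!has_fu] <- 0L

  pid <- c(participants$id, rep.int(participants$id, n_visits))
  visit <- c(rep("baseline", n), unlist(lapply(n_visits[n_visits > 0L], function(k)
    sort(sample(c("year1", "year2", "year3"), k)))))
  dose <- c(base_dose, rep.int(fu_dose, n_visits))

  g <- draw_concentration(dose, cg, params$loq[["gvlm"]])
  s <- draw_concentration(dose, cs, params$loq[["srem"]])
  out <- data.frame(
    participant_id = pid,
    visit = factor(visit, levels = c("baseline", "year1", "year2", "year3")),
    gvlm = g$conc, srem = s$conc,
    below_loq_gvlm = g$below_loq, below_loq_srem = s$below_loq,
    stringsAsFactors = FALSE
  )
  out[order(out$participant_id, out$visit), , drop = FALSE]
}

selfreport_levels <- function() {
  c("adherent", "missed_gt8_per_month", "unsure", "outside_supplement_use")
}

gen_selfreports <- function(params, participants) {
  set.seed(stage_seed(params$seed, "selfreports"))
  n <- nrow(participants)
  dates <- seq(182L, by = 182L, length.out = max(1L, floor(params$followup_years * 365.25 / 182)))
  k <- length(dates)
  p_flag <- ifelse(participants$true_adherent,
                   params$p_selfreport_nonadherent_given_adherent,
                   1 - params$p_selfreport_adherent_given_nonadherent)
  flags <- stats::runif(n) < p_flag
  flag_idx <- rep(NA_integer_, n)
  flag_idx[flags] <- sample.int(k, sum(flags), replace = TRUE)
  flag_status <- rep(NA_character_, n)
  flag_status[flags] <- sample(selfreport_levels()[2:4], sum(flags),
                               replace = TRUE, prob = c(0.7, 0.2, 0.1))

  idx <- rep(seq_len(k), times = n)
  pid <- rep(participants$id, each = k)
  status <- rep("adherent", n * k)
  flagged_rows <- !is.na(flag_idx[pid]) & idx >= flag_idx[pid]
  status[flagged_rows] <- flag_status[pid][flagged_rows]
  data.frame(
    participant_id = pid,
    report_date = dates[idx],
    status = factor(status, levels = selfreport_levels()),
    stringsAsFactors = FALSE
  )
}

gen_events <- function(params, participants) {
  set.seed(stage_seed(params$seed, "events"))
  n <- nrow(participants)
  tau <- params$followup_years
  x <- as.numeric(participants$true_exposed)
  draw <- function(ep) {
    rate <- params$baseline_hazard[[ep]] * exp(params$true_log_hr[[ep]] * x)
    stats::rexp(n, rate)
  }
  t_raw <- vapply(endpoint_levels(), draw, numeric(n))
  death <- t_raw[, "all_cause_mortality"]

  rows <- lapply(endpoint_levels(), function(ep) {
    te <- t_raw[, ep]
    if (ep == "all_cause_mortality") {
      time <- pmin(death, tau)
      event <- death <= tau
    } else {
      lim <- pmin(death, tau)
      time <- pmin(te, lim)
      event <- te <= lim
    }
    data.frame(participant_id = participants$id, endpoint = ep,
               time = time, event = event, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$endpoint <- factor(out$endpoint, levels = endpoint_levels())
  rownames(out) <- NULL
  out
}
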