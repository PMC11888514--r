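test_that("a null two-group exponential dataset recovers HR 1", {
  set.seed(5)
  n <- 3000
  d <- data.frame(exposure = rep(0:1, n / 2))
  t <- rexp(n, 0.1)
  d$time <- pmin(t, 5)
  d$event <- t <= 5
  res <- fit_cox(d)
  expect_lt(abs(res$log_hr), 3 * res$log_hr_se)
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)
})

test_that("the fitted log-HR matches the brute-force partial-likelihood grid", {
  d <- data.frame(time = c(1.1, 2.3, 3.7, 4.1, 5.6, 6.9),
                  event = TRUE,
                  exposure = c(1, 0, 1, 0, 1, 0))
  res <- fit_cox(d)
  oracle <- cox_grid_mle(d$time, d$event, d$exposure)
  expect_equal(res$log_hr, oracle, tolerance = 1e-4)
})

test_that("a generator cohort with perfect classification recovers the true HR", {
  p <- cohort_params(n_total = 20000, seed = 31,
                     p_background_high = 0, p_background_zero = 0.05,
                     p_adherent = 1, p_followup_sample = 1)
  coh <- generate_cohort(p)
  cls <- classify_participants(coh$urine_samples, coh$participants)
  d <- build_survival_dataset(coh, "total_cvd", "biomarker", cls)
  res <- fit_cox(d)
  expect_lt(abs(res$log_hr - log(0.65)), 3 * res$log_hr_se)
})

test_that("per-protocol censoring follows the first non-adherent report", {
  parts <- data.frame(id = 1:3)
  reps <- data.frame(
    participant_id = c(1, 1, 2, 2, 3, 3),
    report_date = c(182, 365, 182, 365, 182, 365),
    status = factor(c("adherent", "adherent",
                      "adherent", "missed_gt8_per_month",
                      "unsure", "adherent"),
                    levels = c("adherent", "missed_gt8_per_month", "unsure",
                               "outside_supplement_use"))
  )
  ct <- pp_censor(parts, reps)
  expect_equal(ct$censor_time, c(Inf, 365 / 365.25, 182 / 365.25))

  # an event at day 500 after a day-365 flag becomes a censoring at day 365
  coh <- list(
    participants = data.frame(id = 1:2,
                              arm = factor(c("intervention", "placebo"),
                                           levels = c("placebo", "intervention"))),
    events = data.frame(participant_id = 1:2, endpoint = "total_cvd",
                        time = 500 / 365.25, event = TRUE),
    self_reports = reps[reps$participant_id %in% 1:2, ]
  )
  d <- build_survival_dataset(coh, "total_cvd", "pp")
  expect_false(d$event[d$id == 2])
  expect_equal(d$time[d$id == 2], 365 / 365.25)
  expect_true(d$event[d$id == 1])
})

test_that("per-protocol analysis never has more events and matches enumeration", {
  coh <- generate_cohort(small_params())
  itt <- build_survival_dataset(coh, "total_cvd", "itt")
  pp <- build_survival_dataset(coh, "total_cvd", "pp")
  expect_lte(sum(pp$event), sum(itt$event))
  # at any time t, the PP risk set is the ITT risk set minus those already
  # censored by the adherence rule (enumerated directly from the reports)
  ct <- pp_censor(coh$participants, coh$self_reports)
  for (t in c(0.5, 1, 2, 3)) {
    itt_risk <- sum(itt$time >= t)
    pp_risk <- sum(pp$time >= t)
    censored_before <- sum(ct$censor_time < t & itt$time >= t &
                             ct$censor_time < itt$time)
    expect_equal(pp_risk, itt_risk - censored_before)
  }
})

test_that("degenerate exposure layouts are flagged not-estimable", {
  d <- data.frame(time = 1:6, event = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE),
                  exposure = 1)
  expect_error(fit_cox(d), class = "flavatrial_not_estimable")
  d2 <- data.frame(time = 1:6, event = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
                   exposure = rep(0:1, each = 3))
  expect_error(fit_cox(d2), class = "flavatrial_not_estimable")
})

test_that("adjusted models fit and report a proportional-hazards test", {
  coh <- generate_cohort(cohort_params(n_total = 4000, seed = 13))
  cls <- classify_participants(coh$urine_samples, coh$participants)
  d <- build_survival_dataset(coh, "total_cvd", "biomarker", cls)
  res <- fit_cox(d, model_spec(2))
  expect_s3_class(res, "cox_result")
  expect_false(is.null(res$ph_test))
  expect_true(res$ph_test[["p"]] >= 0 && res$ph_test[["p"]] <= 1)
  expect_true(all(c("age_at_randomization", "bmi") %in% names(res$knots)))
})

test_that("model nesting holds and the contrast table is complete", {
  expect_true(all(names(model_spec(1)$covariates) %in% names(model_spec(2)$covariates)))
  expect_true(all(names(model_spec(2)$covariates) %in% names(model_spec(3)$covariates)))
  expect_true("arm" %in% names(model_spec(4)$covariates))
  expect_true("ahei" %in% names(model_spec(5)$covariates))

  coh <- generate_cohort(cohort_params(n_total = 2500, seed = 41))
  cls <- classify_participants(coh$urine_samples, coh$participants)
  tab <- run_contrasts(coh, cls, models = 0, endpoints = c("total_cvd", "all_cause_mortality"))
  expect_equal(nrow(tab), 6)
  expect_true(all(!tab$not_estimable))
  expect_true(all(tab$ci_low <= tab$hr & tab$hr <= tab$ci_high))
  # biomarker contrast drops the excluded group
  n_excl <- sum(cls$group == "excluded", na.rm = TRUE)
  expect_equal(unique(tab$n[tab$contrast == "biomarker"]), nrow(coh$participants) - n_excl)
})
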