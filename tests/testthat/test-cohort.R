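test_that("invalid generator parameters are rejected with the field named", {
  expect_error(cohort_params(p_adherent = 1.2), "p_adherent")
  expect_error(cohort_params(p_background_high = NA_real_), "p_background_high")
  expect_error(cohort_params(n_total = 0), "n_total")
  expect_error(cohort_params(baseline_hazard = c(total_cvd = -1, cvd_mortality = 1,
                                                 all_cause_mortality = 1, major_cvd = 1)),
               "baseline_hazard")
  expect_error(cohort_params(true_log_hr = c(total_cvd = Inf, cvd_mortality = 0,
                                             all_cause_mortality = 0, major_cvd = 0)),
               "true_log_hr")
  dr <- default_dose_response()
  dr$sd <- c(0, 0.8)
  expect_error(cohort_params(dose_response = dr), "sd")
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(small_params())
  b <- generate_cohort(small_params())
  expect_identical(a$participants, b$participants)
  expect_identical(a$urine_samples, b$urine_samples)
  expect_identical(a$self_reports, b$self_reports)
  expect_identical(a$events, b$events)
})

test_that("cohort tables satisfy their structural invariants", {
  coh <- generate_cohort(small_params())
  p <- coh$participants
  expect_true(all(p$age_at_randomization >= 60))
  expect_true(all(p$bmi > 0))
  u <- coh$urine_samples
  expect_true(all(u$gvlm >= 0 & u$srem >= 0))
  expect_false(anyDuplicated(paste(u$participant_id, u$visit)) > 0)
  # below-LOQ flag implies stored value under the LOQ
  loq <- small_params()$loq
  expect_true(all(u$gvlm[u$below_loq_gvlm] < loq[["gvlm"]]))
  expect_true(all(u$srem[u$below_loq_srem] < loq[["srem"]]))
  # every participant has a baseline sample
  expect_setequal(u$participant_id[u$visit == "baseline"], p$id)
  sr <- coh$self_reports
  expect_true(all(sr$report_date <= 3.6 * 365.25))
  ev <- coh$events
  expect_true(all(ev$time > 0 & ev$time <= 3.6))
  # all-cause death bounds every other endpoint's observed event time
  death <- ev[ev$endpoint == "all_cause_mortality", ]
  dt <- death$time[match(ev$participant_id, death$participant_id)]
  dd <- death$event[match(ev$participant_id, death$participant_id)]
  other <- ev$endpoint != "all_cause_mortality" & ev$event
  expect_true(all(ev$time[other] <= dt[other] + 1e-12))
})

test_that("degenerate mixtures behave as constructed", {
  # no background, full adherence: intervention follow-up above, placebo below
  p <- cohort_params(n_total = 2000, p_background_high = 0, p_background_zero = 0.05,
                     p_adherent = 1, p_followup_sample = 1, seed = 3)
  coh <- generate_cohort(p)
  st <- classify_samples(coh$urine_samples, cosmos_thresholds())
  fu <- st[st$visit != "baseline", ]
  arm <- coh$participants$arm[match(fu$participant_id, coh$participants$id)]
  expect_gt(mean(fu$above[arm == "intervention"]), 0.95)
  expect_lt(mean(fu$above[arm == "placebo"]), 0.05)
})

test_that("a null effect yields equal event rates in the two arms", {
  p <- cohort_params(n_total = 6000, seed = 17,
                     true_log_hr = c(total_cvd = 0, cvd_mortality = 0,
                                     all_cause_mortality = 0, major_cvd = 0))
  coh <- generate_cohort(p)
  ev <- coh$events[coh$events$endpoint == "total_cvd", ]
  arm <- coh$participants$arm[match(ev$participant_id, coh$participants$id)]
  r1 <- mean(ev$event[arm == "intervention"])
  r0 <- mean(ev$event[arm == "placebo"])
  se <- sqrt(r0 * (1 - r0) * (1 / sum(arm == "placebo") + 1 / sum(arm == "intervention")))
  expect_lt(abs(r1 - r0), 3 * se)
})

test_that("baseline above-threshold fraction matches the mixture-tail oracle", {
  p <- cohort_params(n_total = 50000, seed = 1)
  coh <- generate_cohort(p)
  base <- coh$urine_samples[coh$urine_samples$visit == "baseline", ]
  emp <- mean(classify_samples(base, cosmos_thresholds())$above)
  oracle <- oracle_baseline_above(p)
  se <- sqrt(oracle * (1 - oracle) / nrow(base))
  expect_lt(abs(emp - oracle), 3 * se)
  expect_lt(abs(emp - oracle), 0.01)
})

test_that("self-report misreporting rates match the generator parameters", {
  p <- cohort_params(n_total = 20000, seed = 23)
  coh <- generate_cohort(p)
  flagged_ids <- unique(coh$self_reports$participant_id[
    coh$self_reports$status != "adherent"])
  flagged <- coh$participants$id %in% flagged_ids
  adh <- coh$participants$true_adherent
  # P(ever flags | adherent)
  emp_fa <- mean(flagged[adh])
  se_fa <- sqrt(emp_fa * (1 - emp_fa) / sum(adh))
  expect_lt(abs(emp_fa - p$p_selfreport_nonadherent_given_adherent), 3 * se_fa + 1e-3)
  # P(never flags | non-adherent)
  emp_m <- mean(!flagged[!adh])
  se_m <- sqrt(emp_m * (1 - emp_m) / sum(!adh))
  expect_lt(abs(emp_m - p$p_selfreport_adherent_given_nonadherent), 3 * se_m)
})

test_that("under a null effect the arms' survival curves agree across seeds", {
  alpha <- 0.01
  reject <- vapply(1:100, function(s) {
    p <- cohort_params(n_total = 2000, seed = 1000 + s,
                       true_log_hr = c(total_cvd = 0, cvd_mortality = 0,
                                       all_cause_mortality = 0, major_cvd = 0))
    coh <- generate_cohort(p)
    d <- build_survival_dataset(coh, "total_cvd", "itt")
    lr <- survival::survdiff(survival::Surv(time, event) ~ exposure, data = d)
    (1 - pchisq(lr$chisq, 1)) < alpha
  }, logical(1))
  expect_gte(sum(!reject), 95)
})
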