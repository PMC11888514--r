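thr <- threshold_pair(18.2, 7.8)

test_that("sample classification applies the OR rule with >= at the boundary", {
  s <- data.frame(participant_id = 1:4, visit = "baseline",
                  gvlm = c(20, 0, 18.2, 1), srem = c(1, 0, 0.5, 7.8))
  st <- classify_samples(s, thr)
  expect_identical(st$above, c(TRUE, FALSE, TRUE, TRUE))
  # one missing biomarker: the other decides; both missing is an error
  s2 <- data.frame(participant_id = 1:2, visit = "baseline",
                   gvlm = c(NA, NA), srem = c(9, NA))
  expect_identical(classify_samples(s2[1, ], thr)$above, TRUE)
  expect_error(classify_samples(s2, thr), "missing both")
})

test_that("participant grouping implements the exclusion rule arm-asymmetrically", {
  p <- data.frame(id = 1:5,
                  arm = factor(c("intervention", "placebo", "placebo",
                                 "intervention", "intervention"),
                               levels = c("placebo", "intervention")))
  u <- data.frame(
    participant_id = c(1, 2, 3, 3, 4, 4, 5, 5),
    visit = c("baseline", "baseline", "baseline", "year1",
              "baseline", "year2", "year1", "year3"),
    gvlm = c(1, 1, 20, 1, 1, 1, 5, 25), srem = 0.1
  )
  cls <- classify_participants(u, p, thr)
  expect_equal(as.character(cls$group[cls$participant_id == 1]), "excluded")
  expect_equal(as.character(cls$group[cls$participant_id == 2]), "biomarker_control")
  # baseline above, follow-up below: still active (either-timepoint rule)
  expect_equal(as.character(cls$group[cls$participant_id == 3]), "biomarker_active")
  expect_equal(as.character(cls$group[cls$participant_id == 4]), "biomarker_control")
  # no baseline sample: unclassifiable
  expect_true(cls$unclassifiable[cls$participant_id == 5])
  expect_true(is.na(cls$group[cls$participant_id == 5]))
})

test_that("classification partitions the cohort at any thresholds", {
  coh <- generate_cohort(small_params())
  for (t in list(c(5, 3), c(18.2, 7.8), c(40, 25))) {
    cls <- classify_participants(coh$urine_samples, coh$participants,
                                 threshold_pair(t[1], t[2]))
    n <- table(cls$group, useNA = "ifany")
    expect_equal(sum(n), nrow(coh$participants))
  }
})

test_that("raising thresholds is monotone for counts and exclusions", {
  coh <- generate_cohort(small_params())
  grid <- list(c(5, 3), c(10, 6), c(18.2, 7.8), c(30, 15), c(60, 40))
  prev_active <- Inf
  prev_excl <- -1
  for (t in grid) {
    cls <- classify_participants(coh$urine_samples, coh$participants,
                                 threshold_pair(t[1], t[2]))
    act <- sum(cls$group == "biomarker_active", na.rm = TRUE)
    exc <- sum(cls$group == "excluded", na.rm = TRUE)
    expect_lte(act, prev_active)
    expect_gte(exc, prev_excl)
    prev_active <- act
    prev_excl <- exc
  }
})

test_that("classification is a pure function of samples and thresholds", {
  coh <- generate_cohort(small_params())
  a <- classify_participants(coh$urine_samples, coh$participants, thr)
  b <- classify_participants(coh$urine_samples, coh$participants, thr)
  expect_identical(a, b)
})

test_that("tabulation handles saturated and empty-above cohorts", {
  coh <- generate_cohort(small_params())
  # every sample above: 100% everywhere, nothing excluded
  cls <- classify_participants(coh$urine_samples, coh$participants,
                               threshold_pair(1e-6, 1e-6))
  tab <- tabulate_classification(cls, coh$participants)
  expect_equal(tab$cells$baseline$pct, 100)
  expect_equal(tab$excluded$n, 0)
  expect_equal(tab$n_active, tab$n_analysis)
  # thresholds above every concentration: excluded = intervention arm without follow-up
  cls2 <- classify_participants(coh$urine_samples, coh$participants,
                                threshold_pair(1e6, 1e6))
  tab2 <- tabulate_classification(cls2, coh$participants)
  expect_equal(tab2$cells$baseline$n, 0)
  has_fu <- coh$participants$id %in%
    coh$urine_samples$participant_id[coh$urine_samples$visit != "baseline"]
  expect_equal(tab2$excluded$n,
               sum(coh$participants$arm == "intervention" & !has_fu))
})

test_that("biomarker adherence matches the misclassification-adjusted oracle", {
  p <- cohort_params(n_total = 50000, seed = 2)
  coh <- generate_cohort(p)
  cls <- classify_participants(coh$urine_samples, coh$participants, thr)
  adh <- adherence_summary(cls, coh$self_reports)
  oracle <- 100 * oracle_biomarker_adherence(p)
  se <- 100 * sqrt(oracle / 100 * (1 - oracle / 100) / adh$n_biomarker)
  expect_lt(abs(adh$biomarker_adherence_pct - oracle), 3 * se)
  # all-adherent reports give 100% self-reported adherence
  sr <- coh$self_reports
  sr$status <- factor("adherent", levels = levels(sr$status))
  expect_equal(adherence_summary(cls, sr)$selfreport_adherence_pct, 100)
})
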