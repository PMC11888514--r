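sweep_cohort <- function(n = 2500, seed = 33, ...) {
  generate_cohort(cohort_params(n_total = n, seed = seed, ...))
}

test_that("a single-cell sweep reproduces the standalone biomarker analysis bit-for-bit", {
  coh <- sweep_cohort()
  sw <- sweep_thresholds(coh, grid_gvlm = 18.2, grid_srem = 7.8,
                         endpoints = "total_cvd", model = 2)
  cls <- classify_participants(coh$urine_samples, coh$participants,
                               threshold_pair(18.2, 7.8))
  d <- build_survival_dataset(coh, "total_cvd", "biomarker", cls)
  res <- fit_cox(d, model_spec(2))
  expect_identical(sw$hr, res$hr)
  expect_identical(sw$ci_low, res$ci_low)
  expect_identical(sw$ci_high, res$ci_high)
  expect_identical(sw$n_active, sum(cls$group == "biomarker_active", na.rm = TRUE))
})

test_that("sweeps are deterministic and monotone in the active-group size", {
  coh <- sweep_cohort()
  gg <- c(5, 12, 18.2, 30)
  gs <- c(3, 7.8, 15)
  sw1 <- sweep_thresholds(coh, gg, gs, endpoints = "total_cvd", model = 0)
  sw2 <- sweep_thresholds(coh, gg, gs, endpoints = "total_cvd", model = 0)
  expect_identical(as.data.frame(sw1), as.data.frame(sw2))
  # n_active non-increasing along each grid coordinate
  m <- matrix(sw1$n_active[order(sw1$t_gvlm, sw1$t_srem)], nrow = length(gs))
  expect_true(all(apply(m, 1, diff) <= 0))  # across gvlm
  expect_true(all(apply(m, 2, diff) <= 0))  # across srem
})

test_that("thresholds above every concentration give not-estimable cells", {
  coh <- sweep_cohort(800)
  sw <- sweep_thresholds(coh, 1e6, 1e6, endpoints = "total_cvd")
  expect_true(all(sw$not_estimable))
  expect_true(all(is.na(sw$hr)))
  expect_equal(sw$n_active, 0L)
})

test_that("a sharp bimodal separation makes the surface flat inside the gap", {
  # zero-background diet, full adherence, tiny noise: unexposed samples sit
  # below the LOQ and exposed ones far above the default thresholds, so any
  # threshold inside the gap yields the identical classification and fit
  dr <- default_dose_response()
  dr$sd <- c(0.1, 0.1)
  coh <- sweep_cohort(1200, seed = 44, p_background_high = 0,
                      p_background_zero = 1, p_adherent = 1,
                      p_followup_sample = 1, dose_response = dr)
  sw <- sweep_thresholds(coh, grid_gvlm = c(5, 18.2, 30),
                         grid_srem = c(2, 7.8, 12),
                         endpoints = "total_cvd", model = 0)
  expect_true(all(!sw$not_estimable))
  expect_equal(length(unique(sw$hr)), 1L)
  expect_equal(length(unique(sw$ci_high)), 1L)
})

test_that("stability ranges cover flat surfaces and stop at constructed steps", {
  flat <- expand.grid(t_gvlm = 1:5, t_srem = 1:3)
  flat$endpoint <- "total_cvd"
  flat$hr <- 0.7
  flat$ci_low <- 0.5
  flat$ci_high <- 0.9
  flat$n_active <- 100L
  flat$n_control <- 100L
  flat$not_estimable <- FALSE
  surf <- structure(flat, grid_gvlm = 1:5, grid_srem = 1:3, model_id = 0,
                    class = c("threshold_sweep", "data.frame"))
  rep1 <- stability_report(surf, reference = c(3, 2))
  expect_equal(c(rep1$t_gvlm_min, rep1$t_gvlm_max), c(1, 5))
  expect_equal(c(rep1$t_srem_min, rep1$t_srem_max), c(1, 3))

  step <- surf
  step$ci_high[step$t_gvlm >= 4] <- 1.4   # step breaching tolerance and crossing 1
  rep2 <- stability_report(step, reference = c(2, 2))
  expect_equal(rep2$t_gvlm_max, 3)
  expect_equal(rep2$t_gvlm_min, 1)

  bad <- surf
  bad$not_estimable[bad$t_gvlm == 3 & bad$t_srem == 2] <- TRUE
  expect_error(stability_report(bad, reference = c(3, 2)), "not estimable")
})

test_that("reference thresholds sit inside the stable rectangle of a trial-like cohort", {
  coh <- sweep_cohort(6509, seed = 55)
  sw <- sweep_thresholds(coh, grid_gvlm = c(5, 10, 18.2, 25),
                         grid_srem = c(4, 7.8, 12),
                         endpoints = "total_cvd", model = 0)
  rep <- stability_report(sw, reference = c(18.2, 7.8), tol = 0.10)
  expect_true(rep$t_gvlm_min <= 18.2 && rep$t_gvlm_max >= 18.2)
  expect_true(rep$t_srem_min <= 7.8 && rep$t_srem_max >= 7.8)
})

test_that("the model ladder keeps n constant and inflates the SE under collinearity", {
  coh <- sweep_cohort(6000, seed = 66)
  cls <- classify_participants(coh$urine_samples, coh$participants)
  lad <- model_ladder(coh, cls, endpoints = "total_cvd", models = c(1, 2, 4))
  expect_equal(length(unique(lad$n)), 1L)
  se2 <- lad$log_hr_se[lad$model_id == 2]
  se4 <- lad$log_hr_se[lad$model_id == 4]
  # model 4 adds randomized assignment, collinear with biomarker group
  expect_gte(se4, se2)
})
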