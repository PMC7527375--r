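test_that("annual screening detects grid onsets on time", {
  hist <- make_visits("A", c(0, 0, 1, 3, 3), follow_up = 48)
  out <- simulate_patient(hist, onset_months = 36, make_policy("annual"))
  expect_equal(out$screen_times[[1]], c(0, 12, 24, 36))
  expect_equal(out$detection_time_months, 36)
  expect_false(out$delayed)
  expect_equal(out$delay_months, 0)
  expect_true(out$str_case)
})

test_that("delay is detection minus onset under longer intervals", {
  # 24-month interval from the screen at 0; onset at 12 -> detected at 24
  hist <- make_visits("A", c(0, 3, 3), follow_up = 24)
  fixed24 <- structure(function(state) policy_decision("screen_after", 24),
                       policy_name = NULL)
  out <- simulate_patient(hist, onset_months = 12, fixed24)
  expect_equal(out$detection_time_months, 24)
  expect_true(out$delayed)
  expect_equal(out$delay_months, 12)
})

test_that("guideline schedule follows the hand-traced 0/24/60 pattern", {
  hist <- make_visits("A", rep(0, 6), follow_up = 60)
  out <- simulate_patient(hist, NA, make_policy("guideline"))
  expect_equal(out$screen_times[[1]], c(0, 24, 60))
  expect_equal(out$screens_count, 3)
  expect_false(out$delayed)
  expect_false(out$str_case)
})

test_that("onset at or before the first screen is a contract violation", {
  hist <- make_visits("A", c(3, 3), follow_up = 12)
  expect_error(simulate_patient(hist, 0, make_policy("annual")), "excluded upstream")
})

test_that("an onset beyond the last feasible screen is censored at follow-up", {
  # follow-up 70: screens at 0 and 60 under a fixed 60-month interval;
  # onset at 66 has no later in-window screen
  hist <- make_visits("A", c(0, 0, 0, 0, 0, 2), follow_up = 70)
  fixed60 <- structure(function(state) policy_decision("screen_after", 60),
                       policy_name = NULL)
  out <- simulate_patient(hist, 66, fixed60)
  expect_true(out$delayed)
  expect_true(out$censored)
  expect_equal(out$delay_months, 70 - 66)
  expect_true(is.na(out$detection_time_months))
})

test_that("the event loop matches a month-by-month brute-force oracle on random patients", {
  coh <- generate_cohort(cohort_config(n_patients = 400, seed = 31))
  sel <- select_analysis_cohort(coh)
  imp <- impute_cohort(sel$cohort, "fast", seed = 1)
  params <- default_risk_model()
  ids <- unique(imp$cohort$patient_id)
  set.seed(42)
  ids <- sample(ids, 100)
  policies <- list(make_policy("annual"), make_policy("guideline"),
                   make_policy("personalised", risk_margin = 0.017, params = params))
  onset_of <- setNames(imp$onsets$onset_months, imp$onsets$patient_id)
  for (pid in ids) {
    hist <- imp$cohort[imp$cohort$patient_id == pid, ]
    onset <- onset_of[[pid]]
    pol <- policies[[sample.int(3, 1)]]
    fast <- simulate_patient(hist, onset, pol)
    # oracle sees the policy only through the public state interface
    plain <- switch(attr(pol, "policy_name"),
                    annual = annual_policy,
                    guideline = dutch_guideline_policy,
                    personalised = function(s) personalised_policy(s, 0.017, params))
    slow <- brute_force_sim(hist, onset, plain)
    expect_identical(fast$screen_times[[1]], as.numeric(slow$screen_times))
    expect_equal(fast$delayed, slow$delayed)
    expect_equal(fast$delay_months, slow$delay_months)
    expect_equal(fast$detection_time_months, slow$detection_time_months)
  }
})

test_that("the fast policy branches agree with the generic state interface", {
  coh <- generate_cohort(cohort_config(n_patients = 150, seed = 33))
  sel <- select_analysis_cohort(coh)
  imp <- impute_cohort(sel$cohort, "slow", seed = 1)
  params <- default_risk_model()
  generic <- structure(function(state) personalised_policy(state, 0.02, params),
                       policy_name = NULL)
  a <- simulate_cohort(imp$cohort, imp$onsets, "personalised",
                       risk_margin = 0.02, params = params)
  b <- simulate_cohort(imp$cohort, imp$onsets, generic)
  expect_equal(a$outcomes$screens_count, b$outcomes$screens_count)
  expect_equal(a$outcomes$delay_months, b$outcomes$delay_months)
})

test_that("cohort summaries aggregate delays as reported", {
  hist1 <- make_visits("A", c(0, 3, 3), follow_up = 24)
  hist2 <- make_visits("B", c(0, 0, 0), follow_up = 24)
  coh <- make_cohort(hist1, hist2)
  onsets <- data.frame(patient_id = c("A", "B"), onset_months = c(12, NA))
  fixed24 <- structure(function(state) policy_decision("screen_after", 24),
                       policy_name = NULL)
  res <- simulate_cohort(coh, onsets, fixed24)
  expect_equal(res$summary$delayed, 1)
  expect_equal(res$summary$delay_median, 12)
  expect_equal(res$summary$str_cases, 1)
  expect_equal(res$summary$delayed_pct, 100)
  # no STR cases anywhere: fraction undefined
  res0 <- simulate_cohort(make_cohort(hist2),
                          data.frame(patient_id = "B", onset_months = NA),
                          make_policy("annual"))
  expect_equal(res0$summary$delayed, 0)
  expect_true(is.na(res0$summary$delayed_pct))
})

test_that("delays never exceed 48 months with grid onsets and the 60-month cap", {
  coh <- generate_cohort(cohort_config(n_patients = 1500, seed = 35))
  sel <- select_analysis_cohort(coh)
  for (scen in c("fast", "slow")) {
    imp <- impute_cohort(sel$cohort, scen, seed = 2)
    for (m in c(0.005, 0.02, 0.04)) {
      res <- simulate_cohort(imp$cohort, imp$onsets, "personalised",
                             risk_margin = m, params = default_risk_model())
      expect_true(all(res$outcomes$delay_months <= 48))
    }
  }
})
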