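test_that("response series follows the change-from-baseline definition", {
  co <- toy_cohort()
  r_pos <- compute_response(co)
  r_chg <- compute_response(co, convention = "change_from_baseline")
  # baseline 7.3, visit 6.8: change -0.5, response-positive +0.5
  expect_equal(r_pos$response[r_pos$subject_id == 1],
               c(0.5, 0.4))
  expect_equal(r_chg$response[r_chg$subject_id == 1],
               c(-0.5, -0.4))
  # visit equal to baseline gives zero either way
  co2 <- toy_cohort()
  co2$measurements$hba1c_pct[3] <- 7.5
  expect_equal(compute_response(co2)$response[3], 0)
  # elementwise 5-row check against hand arithmetic
  expect_equal(r_chg$response,
               c(6.8 - 7.3, 6.9 - 7.3, 7.0 - 7.5,
                 6.5 - 7.0, 6.6 - 7.0, 6.4 - 7.0))
  # subjects with no post-baseline measurements are flagged
  co3 <- toy_cohort()
  co3$measurements <- co3$measurements[co3$measurements$subject_id != 2, ]
  expect_message(compute_response(co3), "no post-baseline")
})

test_that("eligibility excludes early events and pre-trial history", {
  co <- toy_cohort()
  # subject with an event before any measurement is excluded
  co$events$event_time_years[1] <- 0.1
  co$events$event_indicator[1] <- 1L
  el <- apply_eligibility(co)
  expect_false(1 %in% el$cohort$baseline$subject_id)
  expect_equal(el$exclusions$n[el$exclusions$reason ==
                                 "no_pre_event_measure"], 1L)
  # edema analyses drop pre-trial history (subject 2 here)
  el2 <- apply_eligibility(toy_cohort(), side_effect_label = "edema")
  expect_false(2 %in% el2$cohort$baseline$subject_id)
  expect_equal(el2$exclusions$n[el2$exclusions$reason ==
                                  "pre_trial_history"], 1L)
  # exclusion counts plus retained count equal the input count
  expect_equal(sum(el2$exclusions$n) + n_subjects(el2$cohort),
               n_subjects(toy_cohort()))
})

test_that("severity filter downgrades non-qualifying events to censoring", {
  co <- toy_cohort()   # subject 1 mild event at 2.0, subject 3 severe
  el <- apply_eligibility(co, severity_filter = "severe")
  ev <- el$cohort$events
  expect_equal(ev$event_indicator[ev$subject_id == 1], 0)
  expect_equal(ev$event_time_years[ev$subject_id == 1], 2.0)
  expect_equal(ev$event_indicator[ev$subject_id == 3], 1)
  expect_equal(el$n_downgraded, 1L)
  el_mod <- apply_eligibility(co, severity_filter = "moderate_plus")
  expect_equal(el_mod$n_downgraded, 1L)
  co_bad <- toy_cohort()
  co_bad$events$severity[1] <- "catastrophic"
  expect_error(apply_eligibility(co_bad), "unknown severity")
})

test_that("eligibility filtering is idempotent", {
  co <- prepared_cohort(seed = 4, n = 150)
  once <- apply_eligibility(co, side_effect_label = "edema")
  twice <- apply_eligibility(once$cohort, side_effect_label = "edema")
  expect_equal(twice$cohort$baseline, once$cohort$baseline)
  expect_equal(twice$cohort$events, once$cohort$events)
  expect_equal(sum(twice$exclusions$n), 0L)
})

test_that("administrative censoring truncates times and measurements", {
  co <- toy_cohort()
  co$events$event_time_years <- c(6.2, 3.0, 1.8)
  co$events$event_indicator <- c(1L, 1L, 1L)
  out <- apply_censoring(co, admin_time = 5)
  expect_equal(out$events$event_time_years, c(5.0, 3.0, 1.8))
  expect_equal(out$events$event_indicator, c(0L, 1L, 1L))
  # measurements after the follow-up end are dropped
  co2 <- toy_cohort()
  co2$events$event_time_years[3] <- 0.5
  out2 <- apply_censoring(co2, admin_time = 5)
  expect_equal(out2$measurements$time_years[
    out2$measurements$subject_id == 3], 0.25)
  # survival-time summary on a seeded 20-subject cohort vs direct rule
  co3 <- generate_cohort(sim_config(n_subjects = 20, seed = 14,
                                    admin_censor_time = 10))
  out3 <- apply_censoring(co3, admin_time = 2)
  expect_equal(out3$events$event_time_years,
               pmin(co3$events$event_time_years, 2))
  expect_true(all(out3$events$event_indicator[
    co3$events$event_time_years > 2] == 0))
})

test_that("counting-process expansion implements exact LOCF intervals", {
  # one measurement, event at 2y: a single interval carrying that value
  co <- toy_cohort()
  co$measurements <- co$measurements[c(1, 3, 4, 5, 6), ]  # subj 1: one meas
  cp <- build_counting_process(co)
  r1 <- cp[cp$subject_id == 1, ]
  expect_equal(nrow(r1), 1L)
  expect_equal(unlist(r1[, c("start", "stop", "event_in_interval")]),
               c(start = 0.5, stop = 2.0, event_in_interval = 1))
  expect_equal(r1$response_at_start, 7.3 - 6.8)
  # censored subject: intervals end at the censoring time with no event
  r2 <- cp[cp$subject_id == 2, ]
  expect_equal(unlist(r2[, c("start", "stop", "event_in_interval")]),
               c(start = 0.5, stop = 1.2, event_in_interval = 0))
  # full three-subject table matches the hand-built fixture
  cp_all <- build_counting_process(toy_cohort())
  expected <- tibble::tibble(
    subject_id = c(1L, 1L, 2L, 3L, 3L, 3L),
    start = c(0.5, 1.0, 0.5, 0.25, 0.75, 1.5),
    stop = c(1.0, 2.0, 1.2, 0.75, 1.5, 1.8),
    event_in_interval = c(0L, 1L, 0L, 0L, 0L, 1L),
    response_at_start = c(0.5, 0.4, 0.5, 0.5, 0.4, 0.6),
    baseline_hba1c = c(7.3, 7.3, 7.5, 7.0, 7.0, 7.0)
  )
  expect_equal(as.data.frame(cp_all), as.data.frame(expected))
})

test_that("counting-process exposure equals follow-up minus first measurement", {
  co <- prepared_cohort(seed = 6, n = 120)
  cp <- build_counting_process(co)
  exposure <- cp |>
    dplyr::summarise(total = sum(stop - start),
                     first = min(start), .by = "subject_id") |>
    dplyr::inner_join(co$events, by = "subject_id")
  expect_equal(exposure$total, exposure$event_time_years - exposure$first)
  # per subject at most one event interval and it is the last
  last_rows <- cp |> dplyr::slice_tail(n = 1, by = "subject_id")
  expect_equal(sum(cp$event_in_interval), sum(last_rows$event_in_interval))
})

test_that("landmark dataset applies delayed entry rules", {
  co <- toy_cohort()
  co$events$event_time_years <- c(0.4, 1.2, 1.8)
  co$events$event_indicator <- c(1L, 0L, 1L)
  lm <- landmark_dataset(co, landmark = 0.5, window = 45 / 365.25)
  # subject 1 had the event before the landmark: excluded
  expect_false(1 %in% lm$subject_id)
  # subject 2 has a measurement exactly at the landmark: retained
  expect_true(2 %in% lm$subject_id)
  expect_equal(lm$measurement_time[lm$subject_id == 2], 0.5)
  expect_equal(lm$entry, rep(0.5, nrow(lm)))
  # nearest measurement wins; ties resolve to the earlier one
  co2 <- toy_cohort()
  co2$measurements <- tibble::tibble(
    subject_id = c(1L, 1L), time_years = c(0.4, 0.6),
    hba1c_pct = c(6.9, 6.7))
  lm2 <- landmark_dataset(co2, landmark = 0.5, window = 0.2)
  expect_equal(lm2$measurement_time[lm2$subject_id == 1], 0.4)
  expect_equal(lm2$response_landmark[lm2$subject_id == 1], 7.3 - 6.9)
  # subject 3 has no measurement in the window: excluded
  expect_false(3 %in% lm2$subject_id)
})
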