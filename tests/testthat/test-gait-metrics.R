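test_that("pause detection scores only excess dwell over the threshold", {
  expect_equal(detect_pauses(cumsum(c(0, rep(0.3, 10))), 0.8), 0)
  times <- cumsum(c(0, 0.3, 0.3, 1.5, 0.3))
  expect_equal(detect_pauses(times, 0.8), 0.7)
  expect_error(detect_pauses(c(0, 0.5, 0.4)), "strictly increasing")
  expect_error(detect_pauses(1.0), "at least 2")
})

test_that("pause-corrected speed formula matches hand arithmetic", {
  expect_equal(eq5_speed(12, 0.30, 4.0), 0.9)
  expect_equal(eq5_speed(12, 0.28, 4.2, 0.36), 0.875)
  # strictly increasing in removed pause time, strictly increasing in d
  tp <- seq(0, 2, by = 0.1)
  v <- eq5_speed(12, 0.28, 4.2, tp)
  expect_true(all(diff(v) > 0))
  expect_error(eq5_speed(12, 0.28, 1.0, 1.0), "corrupt")
  expect_error(eq5_speed(12, 0.28, 4, -0.1), ">= 0")
})

test_that("speed is invariant to a uniform time shift of all events", {
  tr <- list(scenario = "evacuation", site = "x",
             events = data.frame(step_index = 1:12,
                                 crossing_time = cumsum(c(0, rep(0.32, 11)))),
             T = 11 * 0.32, Tp = 0, pfc = 0.08, afc = 0)
  tr_shift <- tr
  tr_shift$events$crossing_time <- tr$events$crossing_time + 100
  expect_equal(descent_speed(tr, 0.28), descent_speed(tr_shift, 0.28))
})

test_that("alone-scenario trials are treated as continuous regardless of dwells", {
  # a long dwell that would count as a pause under detection
  times <- cumsum(c(0, 0.3, 2.0, rep(0.3, 9)))
  tr <- list(scenario = "alone", site = "x",
             events = data.frame(step_index = 1:12, crossing_time = times),
             T = max(times), Tp = NA_real_, pfc = 0.09, afc = -0.02)
  expect_equal(descent_speed(tr, 0.28, pause_handling = "detect"),
               descent_speed(tr, 0.28, pause_handling = "none"))
  tr$scenario <- "evacuation"
  expect_gt(descent_speed(tr, 0.28, pause_handling = "detect"),
            descent_speed(tr, 0.28, pause_handling = "none"))
})

test_that("group summaries report sample statistics and partition the trials", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg)
  stairs <- experiment_staircases()
  t1 <- generate_trials(cohort, stairs$Chengguan, "alone", cfg)
  t2 <- generate_trials(cohort, stairs$Chengguan, "evacuation", cfg)
  all_tr <- structure(c(unclass(t1), unclass(t2)), class = "descent_trial_set",
                      step_depth = 0.28)
  sm <- summarize_trials(all_tr, group_by = "scenario")
  expect_equal(sum(sm$n), length(all_tr))
  expect_equal(nrow(sm), 2)
  expect_true(all(sm$sd_speed >= 0))
  # a single-trial group is flagged degenerate with SD 0
  single <- structure(unclass(t1)[1], class = "descent_trial_set",
                      step_depth = 0.28)
  expect_warning(s1 <- summarize_trials(single, group_by = "scenario"),
                 "single trial")
  expect_equal(s1$sd_speed, 0)
  expect_true(s1$degenerate)
  expect_error(summarize_trials(structure(list(), class = "descent_trial_set"),
                                step_depth = 0.28), "empty")
})

test_that("evacuation summaries recover the generating speed distribution", {
  cfg <- cohort_config(seed = 11) # 72 students
  cohort <- generate_cohort(cfg)
  trials <- generate_trials(cohort, chengguan(), "evacuation", cfg)
  sm <- summarize_trials(trials, group_by = "scenario")
  se <- 0.08 / sqrt(sm$n)
  expect_lt(abs(sm$mean_speed - 0.88), 3 * se)
})

test_that("reference-parameter selection follows the configured policy", {
  sm <- data.frame(
    scenario = c("alone", "paired", "evacuation"),
    mean_speed = c(0.91, 0.82, 0.88), sd_speed = c(0.13, 0.10, 0.08),
    mean_pfc = c(0.094, 0.084, NA), sd_pfc = c(0.02, 0.02, NA),
    n = c(72, 72, 72), stringsAsFactors = FALSE
  )
  ref <- select_reference_parameters(sm, policy = "table5")
  expect_equal(ref$mean[ref$name == "v"], 0.88)
  expect_equal(ref$mean[ref$name == "pfc"], 0.08) # 0.084 rounded to table precision
  expect_equal(ref$mean[ref$name == "afc"], 0)
  ref43 <- select_reference_parameters(sm, policy = "section43")
  expect_equal(ref43$mean[ref43$name == "pfc"], 0.084)
  # scenario selection semantics
  ref_a <- select_reference_parameters(sm, policy = "section43",
                                       v_scenario = "alone")
  expect_equal(ref_a$mean[ref_a$name == "v"], 0.91)
  expect_error(select_reference_parameters(sm[-3, ]), "absent scenario")
})
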