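test_that("cohort generation honours size, stratification and configured means", {
  cfg <- cohort_config(seed = 42)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort), 72)
  expect_equal(as.integer(table(cohort$grade)), rep(12L, 6))
  # per-grade sample mean of l within 3 SE of the configured mean
  for (g in 1:6) {
    p <- cfg$anthro_params[cfg$anthro_params$grade == g, ]
    se <- p$l_sd / sqrt(12)
    expect_lt(abs(mean(cohort$l_m[cohort$grade == g]) - p$l_mean), 3 * se)
  }
  # physical invariants
  expect_true(all(cohort$eta_m > 0 & cohort$eta_m < cohort$L_m))
  expect_true(all(cohort$l_m > 0 & cohort$height_cm > 0))
})

test_that("degenerate SDs collapse the cohort onto the configured means", {
  ap <- default_anthro_params()
  ap[, grep("_sd", names(ap))] <- 0
  cohort <- generate_cohort(cohort_config(anthro_params = ap, seed = 1))
  g3 <- cohort[cohort$grade == 3, ]
  expect_true(all(g3$height_cm == 132))
  expect_true(all(g3$l_m == 0.795))
  expect_true(all(g3$eta_m == 0.11))
})

test_that("identical seed and config give byte-identical cohort CSVs", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(generate_cohort(cohort_config(seed = 9)), f1, row.names = FALSE)
  write.csv(generate_cohort(cohort_config(seed = 9)), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("large-sample draws reproduce the configured distributions", {
  cfg <- cohort_config(n_per_grade = 10000, grades = 3, seed = 5)
  cohort <- generate_cohort(cfg)
  p <- cfg$anthro_params[cfg$anthro_params$grade == 3, ]
  checks <- list(
    c(mean(cohort$l_m), p$l_mean), c(sd(cohort$l_m), p$l_sd),
    c(mean(cohort$height_cm), p$height_mean_cm),
    c(sd(cohort$height_cm), p$height_sd_cm),
    c(mean(cohort$L_m), p$L_mean), c(sd(cohort$L_m), p$L_sd)
  )
  for (ck in checks) expect_lt(abs(ck[1] / ck[2] - 1), 0.02)
  # drawn speeds too, via trials on a 12-step flight
  tr <- generate_trials(cohort, chengguan(), "evacuation", cfg)
  v <- vapply(tr, `[[`, 0, "v_true")
  expect_lt(abs(mean(v) / 0.88 - 1), 0.02)
  expect_lt(abs(sd(v) / 0.08 - 1), 0.02)
})

test_that("pause-free trials round-trip the drawn speed exactly", {
  cfg <- small_config(pause_prob = 0)
  cohort <- generate_cohort(cfg)
  trials <- generate_trials(cohort, chengguan(), "evacuation", cfg)
  for (tr in trials) {
    v_hat <- descent_speed(tr, 0.28)
    expect_equal(v_hat, tr$v_true, tolerance = 1e-9)
  }
})

test_that("continuous scenarios carry no pause time", {
  cfg <- small_config()
  cohort <- generate_cohort(cfg)
  for (scn in c("alone", "paired")) {
    trials <- generate_trials(cohort, chengguan(), scn, cfg)
    expect_true(all(vapply(trials, `[[`, 0, "Tp") == 0))
  }
})

test_that("certain fixed-length pauses add exactly one pause per interval", {
  cfg <- small_config(pause_prob = 1, pause_mean = 0.5, pause_sd = 0)
  cohort <- generate_cohort(cfg)
  trials <- generate_trials(cohort, chengguan(), "evacuation", cfg)
  for (tr in trials) {
    n_int <- nrow(tr$events) - 1
    no_pause_T <- n_int * 0.28 / tr$v_true
    expect_equal(tr$T, no_pause_T + n_int * 0.5, tolerance = 1e-9)
    expect_equal(tr$Tp, n_int * 0.5, tolerance = 1e-12)
  }
})

test_that("generator rejects invalid configurations and scenarios", {
  expect_error(cohort_config(n_per_grade = 0), "positive")
  expect_error(cohort_config(grades = integer(0)), "non-empty")
  expect_error(cohort_config(pause_prob = 1.5), "\\[0, 1\\]")
  cfg <- small_config()
  cohort <- generate_cohort(cfg)
  expect_error(generate_trials(cohort, chengguan(), "sprinting", cfg),
               "unknown scenario")
})

test_that("trial tables round-trip through the long CSV schema", {
  cfg <- small_config(pause_prob = 0)
  cohort <- generate_cohort(cfg)
  trials <- generate_trials(cohort, chengguan(), "evacuation", cfg)
  df <- trials_to_df(trials)
  expect_setequal(names(df), c("subject_id", "trial", "scenario", "site",
                               "step_index", "crossing_time_s", "pfc_m", "afc_m"))
  back <- trials_from_df(df)
  expect_equal(length(back), length(trials))
  # speeds recomputed from the table (pauses re-detected) match the draws
  v_back <- sort(vapply(back, descent_speed, 0, step_depth = 0.28,
                        pause_handling = "detect"))
  v_orig <- sort(vapply(trials, `[[`, 0, "v_true"))
  expect_equal(v_back, v_orig, tolerance = 1e-9)
})
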