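#' Default per-grade anthropometric parameters
#'
#' Grade-stratified means and SDs (12 students per grade in the reference
#' cohort) for age, standing height, shoulder width, pendulum length `l`,
#' foot length `L` and the heel-to-CoP-junction distance `eta`. Heights are
#' carried in centimetres (121-151 cm across grades 1-6), consistent with
#' the height-to-`l` regression. Two printed-source scale oddities are
#' regularised: grade 2-6 height SDs are read as 3-8 cm, and the grade 5
#' foot-length SD as 0.017 m (in line with every other grade).
#'
#' @return A data.frame with one row per grade.
#' @export
default_anthro_params <- function() {
  data.frame(
    grade = 1:6,
    age_mean = c(8.0, 9.0, 10.1, 11.1, 11.3, 12.1),
    age_sd = c(0.0, 0.0, 0.3, 0.7, 0.8, 0.3),
    height_mean_cm = c(121, 127, 132, 140, 148, 151),
    height_sd_cm = c(5.3, 3, 4, 5, 7, 8),
    sw_mean = c(0.286, 0.296, 0.305, 0.315, 0.324, 0.356),
    sw_sd = c(0.02, 0.01, 0.01, 0.01, 0.02, 0.02),
    l_mean = c(0.750, 0.778, 0.795, 0.815, 0.855, 0.865),
    l_sd = c(0.03, 0.03, 0.05, 0.03, 0.02, 0.02),
    L_mean = c(0.216, 0.215, 0.225, 0.224, 0.229, 0.238),
    L_sd = c(0.02, 0.02, 0.02, 0.01, 0.017, 0.01),
    eta_mean = rep(0.11, 6),
    eta_sd = rep(0.01, 6)
  )
}

#' Default scenario-dependent descent-speed parameters
#'
#' Mean and SD of the horizontal descent speed per scenario: descending
#' alone (0.91 +/- 0.13 m/s across sites), in pairs (0.82 +/- 0.10 m/s,
#' midpoint of the observed site means), and under evacuation
#' (0.88 +/- 0.08 m/s, the reference condition for the design bounds).
#'
#' @return A data.frame with columns `scenario`, `mean`, `sd` (m/s).
#' @export
default_speed_params <- function() {
  data.frame(
    scenario = c("alone", "paired", "evacuation"),
    mean = c(0.91, 0.82, 0.88),
    sd = c(0.13, 0.10, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Default foot-clearance parameters per scenario
#'
#' Posterior foot clearance (PFC) is centred near 0.1 m; the paired-scenario
#' mean 0.084 m is the design reference. Anterior foot clearance (AFC) is
#' centred slightly below zero (toes overhanging the step edge). Evacuation
#' clearances are not observable in crowded video frames, so the paired
#' values stand in for that scenario.
#'
#' @return A data.frame with columns `scenario`, `pfc_mean`, `pfc_sd`,
#'   `afc_mean`, `afc_sd` (m).
#' @export
default_clearance_params <- function() {
  data.frame(
    scenario = c("alone", "paired", "evacuation"),
    pfc_mean = c(0.094, 0.084, 0.084),
    pfc_sd = c(0.02, 0.02, 0.02),
    afc_mean = c(-0.020, -0.008, -0.008),
    afc_sd = c(0.02, 0.02, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort and trial generator
#'
#' Bundles all distributional parameters and the RNG seed. Anthropometric
#' and speed distributions are truncated normal (truncated at zero) so that
#' lengths and speeds cannot be negative; AFC is plain normal because
#' negative values are physically meaningful (toe overhang). Within-descent
#' pauses are injected only in the evacuation scenario.
#'
#' @param n_per_grade Students per grade (default 12, i.e. 72 in total).
#' @param grades Integer grade labels (default 1:6).
#' @param anthro_params Per-grade parameter table, see
#'   [default_anthro_params()].
#' @param speed_params Per-scenario speed table, see
#'   [default_speed_params()].
#' @param clearance_params Per-scenario clearance table, see
#'   [default_clearance_params()].
#' @param pause_prob Probability that an inter-step interval carries a pause
#'   (evacuation scenario only). Default 0.3.
#' @param pause_mean,pause_sd Mean and SD of pause length in seconds
#'   (truncated at zero). Defaults 0.5 and 0.2.
#' @param trials_per_subject Trials per subject per scenario (default 1).
#' @param seed Integer RNG seed.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_per_grade = 12, grades = 1:6,
                          anthro_params = default_anthro_params(),
                          speed_params = default_speed_params(),
                          clearance_params = default_clearance_params(),
                          pause_prob = 0.3, pause_mean = 0.5, pause_sd = 0.2,
                          trials_per_subject = 1, seed = 1L) {
  if (n_per_grade < 1) stop("'n_per_grade' must be positive")
  if (length(grades) == 0) stop("'grades' must be non-empty")
  if (!all(grades %in% anthro_params$grade)) {
    stop("every grade must have a row in 'anthro_params'")
  }
  sds <- c(anthro_params$age_sd, anthro_params$height_sd_cm,
           anthro_params$sw_sd, anthro_params$l_sd, anthro_params$L_sd,
           anthro_params$eta_sd, speed_params$sd,
           clearance_params$pfc_sd, clearance_params$afc_sd, pause_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (pause_prob < 0 || pause_prob > 1) stop("'pause_prob' must be in [0, 1]")
  if (any(speed_params$mean <= 0)) stop("speed means must be positive")
  structure(
    list(n_per_grade = as.integer(n_per_grade), grades = as.integer(grades),
         anthro_params = anthro_params, speed_params = speed_params,
         clearance_params = clearance_params, pause_prob = pause_prob,
         pause_mean = pause_mean, pause_sd = pause_sd,
         trials_per_subject = as.integer(trials_per_subject),
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# normal truncated below at `lower`, by redraw; degenerate sd = 0 allowed
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  if (n == 0) return(numeric(0))
  if (all(sd == 0)) return(rep_len(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Generate a synthetic student cohort
#'
#' Draws `n_per_grade` students per grade from the configured per-grade
#' truncated-normal distributions. The constraint `eta < L` (the CoP
#' junction lies on the foot) is enforced by redrawing `eta`. Identical
#' seed and config give identical output.
#'
#' @param config A [cohort_config()] object.
#' @return A data.frame with columns `subject_id`, `grade`, `age`,
#'   `height_cm`, `shoulder_width_m`, `l_m`, `L_m`, `eta_m`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' nrow(cohort) # 72
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_per_grade
  rows <- lapply(config$grades, function(g) {
    p <- config$anthro_params[config$anthro_params$grade == g, ]
    age <- if (p$age_sd == 0) rep(p$age_mean, n) else
      rtrunc_norm(n, p$age_mean, p$age_sd)
    height <- rtrunc_norm(n, p$height_mean_cm, p$height_sd_cm)
    sw <- rtrunc_norm(n, p$sw_mean, p$sw_sd)
    l <- rtrunc_norm(n, p$l_mean, p$l_sd)
    L <- rtrunc_norm(n, p$L_mean, p$L_sd)
    eta <- rtrunc_norm(n, p$eta_mean, p$eta_sd)
    bad <- which(eta >= L)
    while (length(bad)) {
      eta[bad] <- rtrunc_norm(length(bad), p$eta_mean, p$eta_sd)
      bad <- bad[eta[bad] >= L[bad]]
    }
    data.frame(grade = g, age = age, height_cm = height,
               shoulder_width_m = sw, l_m = l, L_m = L, eta_m = eta)
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("S%02d", seq_len(nrow(out))), out)
  out$subject_id <- as.character(out$subject_id)
  rownames(out) <- NULL
  out
}

#' Generate synthetic descent trials
#'
#' Simulates timed traversals of one staircase for every subject in the
#' cohort. A per-trial speed `v` is drawn from the scenario's distribution;
#' step-edge crossing times accumulate one dwell `d / v` per inter-step
#' interval. In the evacuation scenario each interval independently carries
#' a pause with probability `pause_prob`; pause lengths are truncated
#' normal. Per-trial PFC/AFC are drawn from the scenario's clearance
#' distributions.
#'
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param staircase A [staircase_spec()] object with at least 2 steps.
#' @param scenario One of `"alone"`, `"paired"`, `"evacuation"`.
#' @param config A [cohort_config()] object.
#' @param seed RNG seed for the trial draws; defaults to a
#'   scenario-specific offset of `config$seed` so cohort and trial streams
#'   stay independent.
#' @return An object of class `"descent_trial_set"`: a list of trials, each
#'   a list with `subject_id`, `trial`, `scenario`, `site`, `events`
#'   (data.frame `step_index`, `crossing_time`), `pfc`, `afc`, `T`
#'   (total traversal time), `Tp` (injected pause time) and `v_true`.
#' @export
generate_trials <- function(cohort, staircase, scenario, config = cohort_config(),
                            seed = NULL) {
  staircase <- as_staircase_spec(staircase)
  scenarios <- c("alone", "paired", "evacuation")
  if (!scenario %in% scenarios) {
    stop("unknown scenario '", scenario, "'; must be one of ",
         paste(scenarios, collapse = ", "))
  }
  if (staircase$n_steps < 2) stop("staircase must have >= 2 steps")
  if (is.null(seed)) seed <- config$seed + 1000L * match(scenario, scenarios)
  set.seed(seed)
  sp <- config$speed_params[config$speed_params$scenario == scenario, ]
  cp <- config$clearance_params[config$clearance_params$scenario == scenario, ]
  if (nrow(sp) != 1 || nrow(cp) != 1) {
    stop("config lacks speed/clearance parameters for scenario '", scenario, "'")
  }
  d <- staircase$step_depth
  n_steps <- staircase$n_steps
  trials <- list()
  for (i in seq_len(nrow(cohort))) {
    for (r in seq_len(config$trials_per_subject)) {
      v <- rtrunc_norm(1, sp$mean, sp$sd)
      dwell <- rep(d / v, n_steps - 1)
      Tp <- 0
      if (scenario == "evacuation" && config$pause_prob > 0) {
        paused <- stats::runif(n_steps - 1) < config$pause_prob
        if (any(paused)) {
          pauses <- rtrunc_norm(sum(paused), config$pause_mean, config$pause_sd)
          dwell[paused] <- dwell[paused] + pauses
          Tp <- sum(pauses)
        }
      }
      times <- cumsum(c(0, dwell))
      pfc <- rtrunc_norm(1, cp$pfc_mean, cp$pfc_sd)
      afc <- stats::rnorm(1, cp$afc_mean, cp$afc_sd)
      trials[[length(trials) + 1L]] <- list(
        subject_id = cohort$subject_id[i], trial = r, scenario = scenario,
        site = staircase$name,
        events = data.frame(step_index = seq_len(n_steps),
                            crossing_time = times),
        pfc = pfc, afc = afc,
        T = times[n_steps] - times[1], Tp = Tp, v_true = v
      )
    }
  }
  structure(trials, class = "descent_trial_set",
            step_depth = d, seed = seed)
}

#' Convert a trial set to / from the long event table
#'
#' The tabular schema has one row per step-crossing event:
#' `subject_id`, `trial`, `scenario`, `site`, `step_index`,
#' `crossing_time_s`, `pfc_m`, `afc_m`. This is the interchange format for
#' CSV files; the recorded pause time is not part of it and must be
#' recovered with [detect_pauses()] when reading trials back.
#'
#' @param trials A `descent_trial_set`.
#' @return `trials_to_df()`: a long-format data.frame.
#' @export
trials_to_df <- function(trials) {
  do.call(rbind, lapply(trials, function(tr) {
    data.frame(subject_id = tr$subject_id, trial = tr$trial,
               scenario = tr$scenario, site = tr$site,
               step_index = tr$events$step_index,
               crossing_time_s = tr$events$crossing_time,
               pfc_m = tr$pfc, afc_m = tr$afc,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname trials_to_df
#' @param df A long-format event data.frame.
#' @return `trials_from_df()`: a `descent_trial_set` (with `Tp` unset;
#'   pause time is re-estimated downstream).
#' @export
trials_from_df <- function(df) {
  needed <- c("subject_id", "trial", "scenario", "site", "step_index",
              "crossing_time_s", "pfc_m", "afc_m")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  key <- interaction(df$subject_id, df$trial, df$scenario, df$site, drop = TRUE)
  trials <- lapply(split(df, key), function(g) {
    g <- g[order(g$step_index), ]
    list(subject_id = g$subject_id[1], trial = g$trial[1],
         scenario = g$scenario[1], site = g$site[1],
         events = data.frame(step_index = g$step_index,
                             crossing_time = g$crossing_time_s),
         pfc = g$pfc_m[1], afc = g$afc_m[1],
         T = max(g$crossing_time_s) - min(g$crossing_time_s),
         Tp = NA_real_, v_true = NA_real_)
  })
  names(trials) <- NULL
  structure(trials, class = "descent_trial_set")
}
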