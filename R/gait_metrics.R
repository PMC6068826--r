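#' Detect within-descent pauses from step-crossing times
#'
#' A pause is operationalised as the excess of an inter-step dwell over a
#' threshold: `Tp = sum(max(0, dwell_k - dwell_threshold))` over intervals
#' whose dwell exceeds the threshold. The default threshold of 0.8 s is
#' roughly the mean dwell plus two SDs under typical descent speeds, so
#' ordinary stepping is never scored as pausing.
#'
#' @param events A data.frame with a `crossing_time` column (seconds),
#'   ordered by step, or a numeric vector of crossing times.
#' @param dwell_threshold Dwell threshold in seconds, default 0.8.
#' @return Total pause time `Tp` in seconds (0 when no dwell exceeds the
#'   threshold).
#' @examples
#' detect_pauses(c(0, 0.3, 0.6, 2.1, 2.4)) # one 1.5 s dwell -> 0.7 s
#' @export
detect_pauses <- function(events, dwell_threshold = 0.8) {
  times <- if (is.data.frame(events)) events$crossing_time else as.numeric(events)
  if (length(times) < 2) stop("need at least 2 events")
  dwell <- diff(times)
  if (any(dwell <= 0)) stop("crossing times must be strictly increasing")
  sum(pmax(0, dwell - dwell_threshold))
}

#' Pause-corrected horizontal descent speed
#'
#' The horizontal CoM speed over a flight: `v = N * d / (T - Tp)`, where `N`
#' is the number of steps traversed, `d` the step depth, `T` the total
#' traversal time and `Tp` the summed pause time removed from it.
#'
#' @param n_steps Number of steps traversed.
#' @param step_depth Step depth d in m.
#' @param total_time Total traversal time T in s.
#' @param pause_time Summed pause time Tp in s (default 0).
#' @return Speed in m/s.
#' @examples
#' eq5_speed(12, 0.30, 4.0) # 0.9
#' @export
eq5_speed <- function(n_steps, step_depth, total_time, pause_time = 0) {
  if (any(pause_time < 0)) stop("'pause_time' must be >= 0")
  if (any(total_time - pause_time <= 0)) {
    stop("corrupt trial: total time must exceed pause time")
  }
  n_steps * step_depth / (total_time - pause_time)
}

#' Descent speed of one trial
#'
#' Applies the pause-corrected speed formula to a trial's event table. The
#' step count is the number of inter-event intervals, so recomputing the
#' speed of a pause-free synthetic trial returns the generating speed
#' exactly. Pause handling follows the convention that descents alone and
#' in pairs are continuous (`Tp = 0`); only evacuation-scenario trials have
#' pause time removed.
#'
#' @param trial One element of a `descent_trial_set`.
#' @param step_depth Step depth in m.
#' @param pause_handling `"recorded"` uses the trial's stored pause time
#'   when available (falling back to detection); `"detect"` re-estimates it
#'   from dwells with [detect_pauses()]; `"none"` removes nothing.
#' @param dwell_threshold Threshold passed to [detect_pauses()].
#' @return Speed in m/s.
#' @export
descent_speed <- function(trial, step_depth,
                          pause_handling = c("recorded", "detect", "none"),
                          dwell_threshold = 0.8) {
  pause_handling <- match.arg(pause_handling)
  n_int <- nrow(trial$events) - 1
  if (n_int < 1) stop("trial must traverse at least 2 steps")
  Tp <- 0
  if (identical(trial$scenario, "evacuation") && pause_handling != "none") {
    Tp <- if (pause_handling == "recorded" && !is.na(trial$Tp)) trial$Tp
          else detect_pauses(trial$events, dwell_threshold)
  }
  eq5_speed(n_int, step_depth, trial$T, Tp)
}

#' Per-group gait summaries
#'
#' Sample mean and SD (n - 1 denominator) of descent speed, PFC and AFC per
#' scenario/site group. Groups with a single trial get SD 0 and a
#' `degenerate` flag.
#'
#' @param trials A `descent_trial_set`.
#' @param step_depth Step depth in m; defaults to the depth recorded by the
#'   generator on the trial set.
#' @param group_by Grouping columns, subset of `c("scenario", "site")`.
#' @param pause_handling,dwell_threshold Passed to [descent_speed()].
#' @return A data.frame with one row per group: grouping columns,
#'   `mean_speed`, `sd_speed`, `mean_pfc`, `sd_pfc`, `mean_afc`, `sd_afc`,
#'   `n`, `degenerate`.
#' @export
summarize_trials <- function(trials, step_depth = attr(trials, "step_depth"),
                             group_by = c("scenario", "site"),
                             pause_handling = "recorded",
                             dwell_threshold = 0.8) {
  if (length(trials) == 0) stop("empty trial set")
  if (is.null(step_depth)) stop("'step_depth' must be supplied")
  group_by <- match.arg(group_by, c("scenario", "site"), several.ok = TRUE)
  per_trial <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(scenario = tr$scenario, site = tr$site,
               speed = descent_speed(tr, step_depth, pause_handling,
                                     dwell_threshold),
               pfc = tr$pfc, afc = tr$afc, stringsAsFactors = FALSE)
  }))
  key <- interaction(per_trial[group_by], drop = TRUE, sep = "/")
  groups <- split(per_trial, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    sd0 <- function(x) if (n < 2) 0 else stats::sd(x)
    cbind(
      g[1, group_by, drop = FALSE],
      data.frame(mean_speed = mean(g$speed), sd_speed = sd0(g$speed),
                 mean_pfc = mean(g$pfc), sd_pfc = sd0(g$pfc),
                 mean_afc = mean(g$afc), sd_afc = sd0(g$afc),
                 n = n, degenerate = n < 2)
    )
  }))
  rownames(out) <- NULL
  if (any(out$degenerate)) {
    warning("some groups contain a single trial; their SDs are reported as 0")
  }
  out
}

#' Select the reference model parameters from gait summaries
#'
#' The design bounds are evaluated at one reference speed and one reference
#' posterior foot clearance. By default the speed comes from the evacuation
#' scenario (the stampede-relevant condition), the PFC from the paired
#' scenario (closest to crowded descent among the observable scenarios),
#' and the AFC is fixed at zero as an initial-state indicator. The
#' `"table5"` policy additionally rounds the selected means to two decimals
#' -- the precision at which the reference table of the study reports them
#' (e.g. PFC 0.084 -> 0.08) -- while `"section43"` keeps full precision.
#'
#' @param summaries A summary data.frame from [summarize_trials()]
#'   aggregated over sites (i.e. `group_by = "scenario"`), or any data.frame
#'   with columns `scenario`, `mean_speed`, `sd_speed`, `mean_pfc`,
#'   `sd_pfc`, `n`.
#' @param policy `"table5"` (default) or `"section43"`.
#' @param v_scenario Scenario supplying the speed estimate.
#' @param pfc_scenario Scenario supplying the PFC estimate.
#' @return A data.frame of parameter estimates with columns `name`
#'   (`"v"`, `"pfc"`, `"afc"`), `mean`, `sd`, `n`.
#' @export
select_reference_parameters <- function(summaries,
                                        policy = c("table5", "section43"),
                                        v_scenario = "evacuation",
                                        pfc_scenario = "paired") {
  policy <- match.arg(policy)
  pick <- function(scn) {
    rows <- summaries[summaries$scenario == scn, , drop = FALSE]
    if (nrow(rows) == 0) stop("policy references absent scenario '", scn, "'")
    if (nrow(rows) == 1) return(rows)
    # pool sites: n-weighted means, pooled within-site SDs
    wmean <- function(m) sum(m * rows$n) / sum(rows$n)
    pooled_sd <- function(s) sqrt(sum((rows$n - 1) * s^2) /
                                    (sum(rows$n) - nrow(rows)))
    data.frame(scenario = scn,
               mean_speed = wmean(rows$mean_speed),
               sd_speed = pooled_sd(rows$sd_speed),
               mean_pfc = wmean(rows$mean_pfc),
               sd_pfc = pooled_sd(rows$sd_pfc),
               n = sum(rows$n), stringsAsFactors = FALSE)
  }
  vrow <- pick(v_scenario)
  prow <- pick(pfc_scenario)
  v_mean <- vrow$mean_speed
  pfc_mean <- prow$mean_pfc
  if (policy == "table5") {
    v_mean <- round(v_mean, 2)
    pfc_mean <- round(pfc_mean, 2)
  }
  data.frame(
    name = c("v", "pfc", "afc"),
    mean = c(v_mean, pfc_mean, 0),
    sd = c(vrow$sd_speed, prow$sd_pfc, 0),
    n = c(vrow$n, prow$n, prow$n),
    stringsAsFactors = FALSE
  )
}
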