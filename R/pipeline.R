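#' Printed reference table of parameter ranges and step-depth bounds
#'
#' The study's published floating-range table, kept verbatim for
#' discrepancy reporting: per parameter the sample mean and SD, the printed
#' interval estimate, and the printed min/max of the lower ("Minimum") and
#' upper ("Maximum") step-depth bounds, plus the printed totals
#' (0.250, 0.282). Two of its entries are internally inconsistent with the
#' stated t-interval formula (the speed interval) and with its own row
#' extremes (the total maximum); [render_table5()] reports computed values
#' side by side with these.
#'
#' @return A data.frame, one row per parameter.
#' @export
table5_printed <- function() {
  data.frame(
    name = c("pfc", "eta", "v", "l", "N"),
    mean = c(0.08, 0.11, 0.88, 0.81, NA),
    sd = c(0.02, 0.01, 0.08, 0.09, NA),
    ci_low = c(0.075, 0.108, 0.711, 0.789, 7),
    ci_high = c(0.085, 0.112, 0.745, 0.831, 12),
    sdp_min_low = c(0.242, 0.245, 0.241, 0.242, 0.242),
    sdp_min_high = c(0.245, 0.246, 0.250, 0.248, 0.245),
    sdp_max_low = c(0.296, 0.295, 0.291, 0.293, 0.296),
    sdp_max_high = c(0.330, 0.297, 0.302, 0.300, 0.329),
    stringsAsFactors = FALSE
  )
}

#' Printed design totals and final recommendation
#' @return A list with `total` (current design range, m) and `recommended`
#'   (final service-life interval, m) as printed in the study.
#' @export
printed_design_totals <- function() {
  list(total = c(0.250, 0.282), recommended = c(0.258, 0.282))
}

#' Full pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param staircases A list of [staircase_spec()] objects; default the
#'   three experiment sites.
#' @param scenarios Scenarios to simulate.
#' @param alpha Significance level for the t-intervals.
#' @param N_range Integer range of consecutive steps for the design bounds.
#' @param service_life Projection horizon in years.
#' @param policy Reference-parameter policy, `"table5"` or `"section43"`.
#' @param seed Master seed; defaults to the cohort seed.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            staircases = experiment_staircases(),
                            scenarios = c("alone", "paired", "evacuation"),
                            alpha = 0.05, N_range = 7:12, service_life = 30,
                            policy = "table5", seed = cohort$seed) {
  errs <- validate_pipeline_settings(scenarios, alpha, N_range, service_life,
                                     policy)
  if (length(errs)) stop(paste(errs, collapse = "; "))
  cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, staircases = staircases, scenarios = scenarios,
         alpha = alpha, N_range = as.integer(N_range),
         service_life = service_life, policy = policy,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

validate_pipeline_settings <- function(scenarios, alpha, N_range,
                                       service_life, policy) {
  errs <- character(0)
  known <- c("alone", "paired", "evacuation")
  bad <- setdiff(scenarios, known)
  if (length(bad)) {
    errs <- c(errs, paste0("scenarios: unknown value(s) ",
                           paste(bad, collapse = ", ")))
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    errs <- c(errs, "alpha: must be in (0, 1)")
  }
  if (length(N_range) == 0 || min(N_range) > max(N_range)) {
    errs <- c(errs, "N_range: empty range")
  } else if (any(N_range < 2)) {
    errs <- c(errs, "N_range: all values must be >= 2")
  }
  if (!is.numeric(service_life) || service_life < 0) {
    errs <- c(errs, "service_life: must be >= 0")
  }
  if (!policy %in% c("table5", "section43")) {
    errs <- c(errs, "policy: must be 'table5' or 'section43'")
  }
  errs
}

#' Validate a pipeline configuration file
#'
#' Reads a YAML or JSON configuration, cross-validates every field and
#' either returns the constructed [pipeline_config()] or the full list of
#' violations (not fail-fast).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. Recognised keys:
#'   `seed`, `n_per_grade`, `grades`, `pause_prob`, `pause_mean`,
#'   `pause_sd`, `trials_per_subject`, `scenarios`, `alpha`, `N_range`
#'   (two-element `[min, max]`), `service_life`, `policy`, `staircases`
#'   (list of records with `name`, `riser_height`, `step_depth`,
#'   `step_width`, `n_steps`). Omitted keys take package defaults.
#' @return A `pipeline_config` on success; otherwise a character vector of
#'   errors with class `"config_errors"`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  errs <- character(0)
  num_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  g <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]

  n_per_grade <- g("n_per_grade", 12)
  if (!num_ok(n_per_grade) || n_per_grade < 1) {
    errs <- c(errs, "n_per_grade: must be a positive number")
  }
  pause_prob <- g("pause_prob", 0.3)
  if (!num_ok(pause_prob) || pause_prob < 0 || pause_prob > 1) {
    errs <- c(errs, "pause_prob: must be in [0, 1]")
  }
  seed <- g("seed", 1)
  if (!num_ok(seed)) errs <- c(errs, "seed: must be a number")

  staircases <- NULL
  if (!is.null(raw$staircases)) {
    sc_list <- raw$staircases
    if (is.data.frame(sc_list)) sc_list <- split(sc_list, seq_len(nrow(sc_list)))
    staircases <- list()
    for (i in seq_along(sc_list)) {
      s <- as.list(sc_list[[i]])
      res <- tryCatch(
        staircase_spec(s$riser_height, s$step_depth, s$step_width, s$n_steps,
                       incline = s$incline,
                       name = if (is.null(s$name)) paste0("staircase", i) else s$name),
        error = function(e) conditionMessage(e))
      if (is.character(res)) {
        errs <- c(errs, sprintf("staircases[%d]: %s", i, res))
      } else {
        staircases[[res$name]] <- res
      }
    }
  }

  N_range <- g("N_range", c(7, 12))
  if (!is.numeric(N_range) || length(N_range) != 2) {
    errs <- c(errs, "N_range: must be [min, max]")
    N_seq <- 7:12
  } else if (N_range[1] > N_range[2]) {
    errs <- c(errs, "N_range: empty range")
    N_seq <- 7:12
  } else N_seq <- seq(N_range[1], N_range[2])

  scenarios <- g("scenarios", c("alone", "paired", "evacuation"))
  alpha <- g("alpha", 0.05)
  service_life <- g("service_life", 30)
  policy <- g("policy", "table5")
  errs <- c(errs, validate_pipeline_settings(scenarios, alpha, N_seq,
                                             service_life, policy))
  if (length(errs)) return(structure(errs, class = "config_errors"))

  cc <- cohort_config(
    n_per_grade = n_per_grade, grades = g("grades", 1:6),
    pause_prob = pause_prob, pause_mean = g("pause_mean", 0.5),
    pause_sd = g("pause_sd", 0.2),
    trials_per_subject = g("trials_per_subject", 1), seed = seed
  )
  pipeline_config(
    cohort = cc,
    staircases = if (is.null(staircases)) experiment_staircases() else staircases,
    scenarios = scenarios, alpha = alpha, N_range = N_seq,
    service_life = service_life, policy = policy, seed = seed
  )
}

# tiny polynomial rolling hash over the JSON form, for provenance stamping only
config_hash <- function(config) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(config), force = TRUE,
                                      auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full step-depth design pipeline
#'
#' Generates the synthetic cohort and descent trials, summarises gait,
#' selects the reference parameters, estimates confidence intervals,
#' combines the subranges into the current design range, audits each
#' staircase, projects the range over the service life and issues the
#' final recommendation. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory; when given, CSV/JSON artifacts and
#'   a text report are written there.
#' @return An object of class `"audit_report"`: a list with `config_echo`,
#'   `cohort`, `gait_summaries`, `estimates`, `parameter_table`,
#'   `design_range`, `projection`, `recommended`, `audits`, `warnings`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  warnings <- character(0)

  cohort <- generate_cohort(config$cohort)
  all_trials <- list()
  for (s in seq_along(config$staircases)) {
    sc <- config$staircases[[s]]
    for (scn in config$scenarios) {
      tr <- generate_trials(cohort, sc, scn, config$cohort,
                            seed = config$seed + 1000L * s +
                              100L * match(scn, c("alone", "paired", "evacuation")))
      all_trials <- c(all_trials, unclass(tr))
    }
  }
  class(all_trials) <- "descent_trial_set"
  depth_by_site <- vapply(config$staircases, function(s) s$step_depth, 0)
  names(depth_by_site) <- vapply(config$staircases, function(s) s$name, "")

  # per-trial speeds need each site's own depth, so summarise site by site
  by_site <- lapply(names(depth_by_site), function(site) {
    sub <- Filter(function(tr) tr$site == site, all_trials)
    class(sub) <- "descent_trial_set"
    summarize_trials(sub, step_depth = depth_by_site[[site]],
                     group_by = c("scenario", "site"))
  })
  gait_summaries <- do.call(rbind, by_site)

  # scenario-level pooling for the reference parameters
  scen_summaries <- do.call(rbind, lapply(unique(gait_summaries$scenario),
    function(scn) {
      rows <- gait_summaries[gait_summaries$scenario == scn, ]
      wmean <- function(m) sum(m * rows$n) / sum(rows$n)
      pooled_sd <- function(s) sqrt(sum((rows$n - 1) * s^2) /
                                      max(1, sum(rows$n) - nrow(rows)))
      data.frame(scenario = scn, mean_speed = wmean(rows$mean_speed),
                 sd_speed = pooled_sd(rows$sd_speed),
                 mean_pfc = wmean(rows$mean_pfc),
                 sd_pfc = pooled_sd(rows$sd_pfc),
                 mean_afc = wmean(rows$mean_afc),
                 sd_afc = pooled_sd(rows$sd_afc),
                 n = sum(rows$n), stringsAsFactors = FALSE)
    }))

  ref <- select_reference_parameters(scen_summaries, policy = config$policy)
  anthro <- data.frame(
    name = c("eta", "l", "L"),
    mean = c(mean(cohort$eta_m), mean(cohort$l_m), mean(cohort$L_m)),
    sd = c(stats::sd(cohort$eta_m), stats::sd(cohort$l_m),
           stats::sd(cohort$L_m)),
    n = nrow(cohort), stringsAsFactors = FALSE
  )
  if (config$policy == "table5") {
    anthro$mean[anthro$name != "L"] <- round(anthro$mean[anthro$name != "L"], 2)
    anthro$mean[anthro$name == "L"] <- round(anthro$mean[anthro$name == "L"], 3)
  }
  estimates <- rbind(ref[ref$name %in% c("v", "pfc"), ], anthro)

  ptable <- parameter_table(estimates, alpha = config$alpha,
                            N_range = config$N_range)
  printed <- table5_printed()
  v_ci <- c(ptable$ci_low[ptable$name == "v"], ptable$ci_high[ptable$name == "v"])
  if (abs(v_ci[1] - printed$ci_low[printed$name == "v"]) > 0.02) {
    warnings <- c(warnings, sprintf(
      "speed interval (%.3f, %.3f) computed from the t-formula differs from the printed (%.3f, %.3f); the printed value is inconsistent with the stated formula",
      v_ci[1], v_ci[2], printed$ci_low[printed$name == "v"],
      printed$ci_high[printed$name == "v"]))
  }

  dr <- combine_subranges(ptable, N_range = config$N_range)
  projection <- project_design_range(
    estimates, height_cm = mean(cohort$height_cm),
    horizon = config$service_life, alpha = config$alpha,
    N_range = config$N_range)
  projected_final <- c(projection$d_low[nrow(projection)],
                       projection$d_high[nrow(projection)])
  recommended <- recommend_range(c(dr$d_low, dr$d_high), projected_final)

  params_hat <- model_params(
    v = estimates$mean[estimates$name == "v"],
    l = estimates$mean[estimates$name == "l"],
    L = estimates$mean[estimates$name == "L"],
    eta = estimates$mean[estimates$name == "eta"],
    pfc = estimates$mean[estimates$name == "pfc"])
  audits <- lapply(config$staircases, function(sc) {
    audit_staircase(sc, params_hat,
                    N_range = config$N_range[config$N_range <= sc$n_steps])
  })

  report <- structure(
    list(
      config_echo = list(seed = config$seed, alpha = config$alpha,
                         N_range = config$N_range,
                         service_life = config$service_life,
                         policy = config$policy,
                         scenarios = config$scenarios,
                         n_subjects = nrow(cohort),
                         config_hash = config_hash(config),
                         schema_version = "1"),
      cohort = cohort,
      trials = all_trials,
      gait_summaries = gait_summaries,
      scenario_summaries = scen_summaries,
      estimates = estimates,
      parameter_table = as.data.frame(ptable),
      design_range = dr,
      projection = projection,
      recommended = recommended,
      audits = audits,
      warnings = warnings
    ),
    class = "audit_report"
  )
  if (!is.null(output_dir)) write_report_artifacts(report, output_dir)
  report
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Step-depth design report (seed", x$config_echo$seed, ")\n")
  cat(sprintf("  current design range:   [%.3f, %.3f] m\n",
              x$design_range$d_low, x$design_range$d_high))
  cat(sprintf("  projected (+%d y):      [%.3f, %.3f] m\n",
              x$config_echo$service_life,
              x$projection$d_low[nrow(x$projection)],
              x$projection$d_high[nrow(x$projection)]))
  cat(sprintf("  recommended:            [%.3f, %.3f] m (prefer %.3f)\n",
              x$recommended[1], x$recommended[2],
              attr(x$recommended, "preferred")))
  for (a in x$audits) {
    cat(sprintf("  %-10s d = %.2f m: %s\n", a$staircase$name,
                a$staircase$step_depth, if (a$safe) "SAFE" else "UNSAFE"))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

write_report_artifacts <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  utils::write.csv(report$cohort, p("cohort.csv"), row.names = FALSE)
  utils::write.csv(trials_to_df(report$trials), p("trials.csv"),
                   row.names = FALSE)
  utils::write.csv(report$gait_summaries, p("gait_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$parameter_table, p("parameter_table.csv"),
                   row.names = FALSE)
  render_table5(report, csv = p("table5.csv"), text = p("table5.txt"))
  json <- list(
    schema_version = "1",
    config = report$config_echo,
    estimates = report$estimates,
    design_range = list(d_low = report$design_range$d_low,
                        d_high = report$design_range$d_high,
                        subranges = report$design_range$subranges),
    projection = report$projection,
    recommended = list(lower = unname(report$recommended[1]),
                       upper = unname(report$recommended[2]),
                       preferred = attr(report$recommended, "preferred")),
    audits = lapply(report$audits, function(a) {
      list(name = a$staircase$name, step_depth = a$staircase$step_depth,
           d_low = a$d_low, d_high = a$d_high, safe = a$safe)
    }),
    warnings = report$warnings
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Render the parameter-range table with printed-value comparison
#'
#' Produces the floating-range table in the shape of the study's published
#' version: per parameter the sample mean, SD, computed confidence
#' interval, the min/max of each design bound under its sweep, and a
#' discrepancy column against the printed values.
#'
#' @param report An `audit_report` from [run_pipeline()], or a list with
#'   `parameter_table` and `design_range` entries.
#' @param csv,text Optional output paths.
#' @return The comparison data.frame, invisibly when files are written.
#' @export
render_table5 <- function(report, csv = NULL, text = NULL) {
  if (is.null(report$parameter_table) || is.null(report$design_range)) {
    stop("report must contain 'parameter_table' and 'design_range'")
  }
  pt <- report$parameter_table
  sub <- report$design_range$subranges
  printed <- table5_printed()
  rows <- lapply(printed$name, function(nm) {
    ci <- c(pt$ci_low[pt$name == nm], pt$ci_high[pt$name == nm])
    sw <- sub[sub$parameter == nm, ]
    pr <- printed[printed$name == nm, ]
    data.frame(
      parameter = nm,
      mean = pt$mean[pt$name == nm], sd = pt$sd[pt$name == nm],
      ci_low = round(ci[1], 3), ci_high = round(ci[2], 3),
      printed_ci_low = pr$ci_low, printed_ci_high = pr$ci_high,
      ci_discrepancy = round(max(abs(ci - c(pr$ci_low, pr$ci_high))), 3),
      lower_min = round(sw$lower_min, 3), lower_max = round(sw$lower_max, 3),
      upper_min = round(sw$upper_min, 3), upper_max = round(sw$upper_max, 3),
      printed_lower_min = pr$sdp_min_low, printed_lower_max = pr$sdp_min_high,
      printed_upper_min = pr$sdp_max_low, printed_upper_max = pr$sdp_max_high,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  totals <- printed_design_totals()
  tot <- data.frame(
    parameter = "total", mean = NA, sd = NA, ci_low = NA, ci_high = NA,
    printed_ci_low = NA, printed_ci_high = NA, ci_discrepancy = NA,
    lower_min = NA, lower_max = round(report$design_range$d_low, 3),
    upper_min = round(report$design_range$d_high, 3), upper_max = NA,
    printed_lower_min = NA, printed_lower_max = totals$total[1],
    printed_upper_min = totals$total[2], printed_upper_max = NA,
    stringsAsFactors = FALSE
  )
  tab <- rbind(tab, tot)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  if (!is.null(text)) {
    lines <- c(
      "Floating range of parameters and design range of step depth",
      sprintf("  computed totals: d_low = %.3f, d_high = %.3f (printed: %.3f, %.3f)",
              report$design_range$d_low, report$design_range$d_high,
              totals$total[1], totals$total[2]),
      utils::capture.output(print(tab, row.names = FALSE))
    )
    writeLines(lines, text)
  }
  if (is.null(csv) && is.null(text)) tab else invisible(tab)
}
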