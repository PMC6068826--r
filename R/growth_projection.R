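#' Fit a linear growth trend
#'
#' Ordinary least squares of a body measurement on time (calendar year or
#' age offset). Constant series are degenerate: the slope is 0 and R^2 is
#' reported as 0 with a flag.
#'
#' @param time Numeric time axis (>= 3 points, non-constant).
#' @param value Measurement in cm.
#' @param variable Label, `"height"` or `"foot_length"`.
#' @return An object of class `"growth_model"`: list with `slope`
#'   (cm/year), `intercept` (cm), `r_squared`, `variable`, `degenerate`.
#' @export
fit_trend <- function(time, value, variable = c("height", "foot_length")) {
  variable <- match.arg(variable)
  if (length(time) < 3 || length(value) != length(time)) {
    stop("need at least 3 (time, value) points")
  }
  if (stats::var(time) == 0) stop("zero variance in 'time'")
  fit <- stats::lm(value ~ time)
  degenerate <- stats::var(value) == 0
  # R^2 from the decomposition directly; summary() warns on perfect fits
  r2 <- if (degenerate) 0 else
    1 - sum(stats::residuals(fit)^2) / sum((value - mean(value))^2)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, variable = variable, degenerate = degenerate),
    class = "growth_model"
  )
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model> %s: %.4f cm/year + %.3f cm (R^2 = %.2f)%s\n",
              x$variable, x$slope, x$intercept, x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Default growth trends for Chinese primary-school pupils
#'
#' Linear trends fitted to national height and foot-length records of 7-12
#' year olds: height 0.4359 cm/year (R^2 = 0.98), foot length 0.1629
#' cm/year (R^2 = 0.97). The intercept convention (calendar-year offset) is
#' inert for projection, where only the slopes matter.
#'
#' @return A named list of two `growth_model` objects, `height` and
#'   `foot_length`.
#' @export
default_growth_models <- function() {
  list(
    height = structure(list(slope = 0.4359, intercept = 78.033,
                            r_squared = 0.98, variable = "height",
                            degenerate = FALSE), class = "growth_model"),
    foot_length = structure(list(slope = 0.1629, intercept = 18.208,
                                 r_squared = 0.97, variable = "foot_length",
                                 degenerate = FALSE), class = "growth_model")
  )
}

#' Pendulum length from standing height
#'
#' The cohort regression of CoM-to-ankle distance on height:
#' `l = (0.3484 * height_cm + 33.518) / 100` metres (R^2 = 0.73 in the
#' study cohort). The fit was made on 121-151 cm children; below about
#' 100 cm it is an extrapolation.
#'
#' @param height_cm Standing height in cm (> 0).
#' @param coef Regression coefficients `c(slope, intercept)` in cm.
#' @return Pendulum length in metres. Vectorised over `height_cm`.
#' @examples
#' l_from_height(136) # about 0.809
#' @export
l_from_height <- function(height_cm, coef = c(slope = 0.3484, intercept = 33.518)) {
  if (any(height_cm <= 0)) stop("'height_cm' must be positive")
  if (any(height_cm < 100)) {
    warning("height below 100 cm: regression used outside its fitted range")
  }
  (coef[["slope"]] * height_cm + coef[["intercept"]]) / 100
}

#' Project model parameters over a service horizon
#'
#' Advances height and foot length by their linear growth slopes, recomputes
#' the pendulum length from the projected height, and holds speed, PFC and
#' eta fixed (no trend is assumed for them). One row is produced per
#' decade from 0 to `horizon` (plus the horizon itself if not on a decade).
#'
#' @param params A [model_params()] object (current values).
#' @param height_cm Current mean standing height in cm used as the
#'   projection anchor (default 136).
#' @param models Growth models, see [default_growth_models()].
#' @param horizon Service horizon in years (>= 0).
#' @param l_coef Coefficients for [l_from_height()].
#' @return A data.frame with one row per time point: `years`, `height_cm`,
#'   `v`, `l`, `L`, `eta`, `pfc`.
#' @export
project_params <- function(params, height_cm = 136,
                           models = default_growth_models(), horizon = 30,
                           l_coef = c(slope = 0.3484, intercept = 33.518)) {
  params <- as_model_params(params)
  if (horizon < 0) stop("'horizon' must be >= 0")
  years <- unique(c(seq(0, horizon, by = 10), horizon))
  h <- height_cm + models$height$slope * years
  l <- l_from_height(h, coef = l_coef)
  # anchor at the current cohort values: project the increments, not levels
  l <- params$l + (l - l_from_height(height_cm, coef = l_coef))
  L <- params$L + models$foot_length$slope * years / 100
  data.frame(years = years, height_cm = h, v = params$v, l = l, L = L,
             eta = params$eta, pfc = params$pfc)
}

#' Project the step-depth design range over a service horizon
#'
#' Re-runs the interval estimation and subrange combination at each
#' projected time point, shifting the means of pendulum length and foot
#' length by their growth increments while keeping the SDs, sample size
#' and all other parameters at their current values.
#'
#' @param estimates Current parameter estimates, see
#'   [reference_estimates()].
#' @param height_cm Current mean standing height in cm.
#' @param models Growth models.
#' @param horizon Service horizon in years.
#' @param alpha Significance level for the t-intervals.
#' @param N_range Integer range of consecutive steps.
#' @param l_coef Coefficients for [l_from_height()].
#' @return A data.frame with one row per time point: `years`, `l_mean`,
#'   `L_mean`, `d_low`, `d_high`.
#' @export
project_design_range <- function(estimates = reference_estimates(),
                                 height_cm = 136,
                                 models = default_growth_models(),
                                 horizon = 30, alpha = 0.05, N_range = 7:12,
                                 l_coef = c(slope = 0.3484, intercept = 33.518)) {
  base <- model_params(
    v = estimates$mean[estimates$name == "v"],
    l = estimates$mean[estimates$name == "l"],
    L = estimates$mean[estimates$name == "L"],
    eta = estimates$mean[estimates$name == "eta"],
    pfc = estimates$mean[estimates$name == "pfc"]
  )
  proj <- project_params(base, height_cm, models, horizon, l_coef)
  out <- do.call(rbind, lapply(seq_len(nrow(proj)), function(i) {
    est <- estimates
    est$mean[est$name == "l"] <- proj$l[i]
    est$mean[est$name == "L"] <- proj$L[i]
    dr <- combine_subranges(parameter_table(est, alpha, N_range))
    data.frame(years = proj$years[i], l_mean = proj$l[i], L_mean = proj$L[i],
               d_low = dr$d_low, d_high = dr$d_high)
  }))
  rownames(out) <- NULL
  out
}

#' Final service-life recommendation for step depth
#'
#' Combines the current and end-of-horizon design ranges: the lower bound
#' is taken from the projection (taller future pupils drift further per
#' step, so the minimum safe depth grows), the upper bound from the current
#' range (present building constraints). Within the recommended interval
#' the larger depth is preferred, as a reserve against behavioural
#' deviations.
#'
#' @param current Current design range: a `design_range` object or a
#'   numeric `c(d_low, d_high)`.
#' @param projected End-of-horizon design range, same forms.
#' @return Named numeric vector `c(lower, upper)` in metres, with attribute
#'   `preferred` (= the upper value).
#' @examples
#' recommend_range(c(0.250, 0.282), c(0.258, 0.294)) # 0.258 0.282
#' @export
recommend_range <- function(current, projected) {
  as_pair <- function(x) {
    if (inherits(x, "design_range")) c(x$d_low, x$d_high) else as.numeric(x)
  }
  cur <- as_pair(current)
  proj <- as_pair(projected)
  if (proj[1] >= cur[2]) {
    stop(sprintf(
      "no feasible recommendation: projected lower bound %.3f >= current upper bound %.3f",
      proj[1], cur[2]))
  }
  out <- c(lower = proj[1], upper = cur[2])
  attr(out, "preferred") <- unname(cur[2])
  out
}
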