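#' Two-sided Student-t confidence interval for a mean
#'
#' `mean +/- t_{alpha/2}(n - 1) * sd / sqrt(n)`. All arithmetic is at full
#' precision; round for display only.
#'
#' @param mean Sample mean.
#' @param sd Sample SD (n - 1 denominator).
#' @param n Sample size (>= 2).
#' @param alpha Two-sided significance level, default 0.05.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' round(t_interval(0.08, 0.02, 72), 3) # 0.075 0.085
#' @export
t_interval <- function(mean, sd, n, alpha = 0.05) {
  if (n < 2) stop("'n' must be >= 2")
  if (sd < 0) stop("'sd' must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  half <- stats::qt(1 - alpha / 2, df = n - 1) * sd / sqrt(n)
  c(low = mean - half, high = mean + half)
}

#' Reference parameter estimates of the study cohort
#'
#' The sample means and SDs (n = 72) used as default inputs to the design
#' range: PFC 0.08 +/- 0.02 m, eta 0.11 +/- 0.01 m, speed 0.88 +/- 0.08
#' m/s, pendulum length 0.81 +/- 0.09 m, foot length 0.224 +/- 0.02 m.
#'
#' @return A data.frame with columns `name`, `mean`, `sd`, `n`.
#' @export
reference_estimates <- function() {
  data.frame(
    name = c("pfc", "eta", "v", "l", "L"),
    mean = c(0.08, 0.11, 0.88, 0.81, 0.224),
    sd = c(0.02, 0.01, 0.08, 0.09, 0.02),
    n = 72L,
    stringsAsFactors = FALSE
  )
}

#' Interval-estimation table of the design parameters
#'
#' Computes the two-sided t-interval for every continuous model parameter
#' and appends the consecutive-step count `N` as a fixed integer range.
#' Foot length `L` enters the upper design bound at its sample mean only,
#' so its CI is computed for reporting but not swept.
#'
#' @param estimates A data.frame with columns `name`, `mean`, `sd`, `n`,
#'   containing at least `pfc`, `eta`, `v`, `l`, `L`. Default
#'   [reference_estimates()].
#' @param alpha Two-sided significance level, default 0.05.
#' @param N_range Integer range of consecutive steps, default `7:12`.
#' @return An object of class `"parameter_table"`: a data.frame with
#'   columns `name`, `mean`, `sd`, `n`, `ci_low`, `ci_high` plus an `N` row
#'   whose interval is the fixed range; the `alpha` and `N_range` are
#'   stored as attributes.
#' @export
parameter_table <- function(estimates = reference_estimates(), alpha = 0.05,
                            N_range = 7:12) {
  required <- c("pfc", "eta", "v", "l", "L")
  missing <- setdiff(required, estimates$name)
  if (length(missing)) {
    stop("missing required parameter(s): ", paste(missing, collapse = ", "))
  }
  est <- estimates[match(required, estimates$name), ]
  ci <- t(mapply(t_interval, est$mean, est$sd, est$n,
                 MoreArgs = list(alpha = alpha)))
  out <- data.frame(name = est$name, mean = est$mean, sd = est$sd, n = est$n,
                    ci_low = ci[, 1], ci_high = ci[, 2],
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(name = "N", mean = NA_real_, sd = NA_real_,
                               n = NA_integer_, ci_low = min(N_range),
                               ci_high = max(N_range)))
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "N_range") <- as.integer(N_range)
  class(out) <- c("parameter_table", "data.frame")
  out
}

#' Combine per-parameter subranges into the step-depth design range
#'
#' One-at-a-time sweeps: each parameter in `pfc`, `eta`, `v`, `l` is set to
#' the endpoints of its confidence interval (and `N` to each integer in its
#' range) while the others stay at their sample means; the closed-form
#' lower and upper step-depth bounds are evaluated over the whole `N`
#' range at every sweep point. The design range is then
#' `d_low = max` of all recorded lower-bound values and
#' `d_high = min` of all recorded upper-bound values, i.e. the depth range
#' safe under every parameter excursion considered. A full-factorial sweep
#' over all CI-endpoint combinations is available via `sweep = "factorial"`.
#'
#' @param table A [parameter_table()].
#' @param N_range Integer range of consecutive steps; defaults to the range
#'   stored on `table`.
#' @param g Gravity in m/s^2.
#' @param sweep `"one_at_a_time"` (default) or `"factorial"`.
#' @return An object of class `"design_range"`: a list with `d_low`,
#'   `d_high`, `subranges` (per parameter and bound, the min and max over
#'   its sweep), and `provenance` (inputs and rule used).
#' @export
combine_subranges <- function(table, N_range = attr(table, "N_range"),
                              g = 9.81, sweep = c("one_at_a_time", "factorial")) {
  sweep <- match.arg(sweep)
  if (is.null(N_range)) N_range <- 7:12
  N_range <- as.integer(N_range)
  if (length(N_range) == 0 || any(N_range < 2)) {
    stop("'N_range' must be a non-empty set of integers >= 2")
  }
  get <- function(p, what = "mean") table[table$name == p, what]
  means <- list(pfc = get("pfc"), eta = get("eta"), v = get("v"),
                l = get("l"), L = get("L"))
  cis <- lapply(c(pfc = "pfc", eta = "eta", v = "v", l = "l"), function(p) {
    c(get(p, "ci_low"), get(p, "ci_high"))
  })

  eval_bounds <- function(pfc, eta, v, l) {
    dcom <- delta_com(v, l, g)
    list(lower = sdp_lower_bound(pfc, eta, dcom, N_range),
         upper = sdp_upper_bound(pfc, means$L, dcom, N_range))
  }

  if (sweep == "one_at_a_time") {
    sub <- list()
    for (p in c("pfc", "eta", "v", "l")) {
      vals <- lapply(cis[[p]], function(x) {
        args <- means[c("pfc", "eta", "v", "l")]
        args[[p]] <- x
        do.call(eval_bounds, args)
      })
      sub[[p]] <- list(lower = range(unlist(lapply(vals, `[[`, "lower"))),
                       upper = range(unlist(lapply(vals, `[[`, "upper"))))
    }
    at_means <- do.call(eval_bounds, means[c("pfc", "eta", "v", "l")])
    sub[["N"]] <- list(lower = range(at_means$lower),
                       upper = range(at_means$upper))
    lows <- unlist(lapply(sub, function(s) s$lower))
    highs <- unlist(lapply(sub, function(s) s$upper))
  } else {
    grid <- expand.grid(pfc = cis$pfc, eta = cis$eta, v = cis$v, l = cis$l)
    vals <- lapply(seq_len(nrow(grid)), function(i) {
      eval_bounds(grid$pfc[i], grid$eta[i], grid$v[i], grid$l[i])
    })
    lows <- unlist(lapply(vals, `[[`, "lower"))
    highs <- unlist(lapply(vals, `[[`, "upper"))
    sub <- list(factorial = list(lower = range(lows), upper = range(highs)))
  }

  d_low <- max(lows)
  d_high <- min(highs)
  if (d_low >= d_high) {
    stop(sprintf("infeasible combination: d_low %.4f >= d_high %.4f",
                 d_low, d_high))
  }
  subranges <- do.call(rbind, lapply(names(sub), function(p) {
    data.frame(parameter = p,
               lower_min = sub[[p]]$lower[1], lower_max = sub[[p]]$lower[2],
               upper_min = sub[[p]]$upper[1], upper_max = sub[[p]]$upper[2],
               stringsAsFactors = FALSE)
  }))
  structure(
    list(d_low = d_low, d_high = d_high, subranges = subranges,
         provenance = list(rule = sweep, N_range = N_range, g = g,
                           inputs = as.data.frame(table))),
    class = "design_range"
  )
}

#' @export
print.design_range <- function(x, ...) {
  cat(sprintf("<design_range> step depth in [%.3f, %.3f] m (rule: %s, N in {%s})\n",
              x$d_low, x$d_high, x$provenance$rule,
              paste(x$provenance$N_range, collapse = ",")))
  invisible(x)
}
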