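#' Per-step anterior drift of the extrapolated centre of mass
#'
#' During single-support stair descent the body is modelled as an inverted
#' pendulum pivoting about the stance ankle. The extrapolated centre of mass
#' (XCoM) leads the vertical CoM projection by `v / omega0`, where
#' `omega0 = sqrt(g / l)` is the pendulum eigenfrequency. Each step therefore
#' advances the projected CoM by `v * sqrt(l / g)` relative to the tread it
#' lands on.
#'
#' @param v Horizontal CoM speed in m/s (non-negative).
#' @param l Pendulum length in m: distance from the whole-body CoM to the
#'   ankle joint centre. Must be positive.
#' @param g Gravitational acceleration in m/s^2, default 9.81.
#' @return Anterior drift per step, in metres. Vectorised over all arguments.
#' @examples
#' delta_com(0.88, 0.81) # about 0.253 m
#' @export
delta_com <- function(v, l, g = 9.81) {
  if (any(l <= 0)) stop("pendulum length 'l' must be positive")
  if (any(g <= 0)) stop("gravity 'g' must be positive")
  if (any(v < 0)) stop("speed 'v' must be non-negative")
  v * sqrt(l / g)
}

#' Minimum safe step depth for an N-step flight
#'
#' After descending `N - 1` steps the centre of pressure must still lie
#' within the Nth tread. With the CoP starting `pfc + eta` from the first
#' riser and drifting `dcom` per step, safety requires
#' `pfc + eta + (N - 1) * dcom <= N * d`, giving the lower design bound
#' `d >= (pfc + eta + (N - 1) * dcom) / N`.
#'
#' @param pfc Posterior foot clearance in m (riser-to-heel gap).
#' @param eta Heel-to-CoP-junction distance in m (the critical CoP sits at
#'   the midfoot/forefoot junction, `eta` along the foot from the heel).
#' @param dcom Per-step CoM drift in m, see [delta_com()].
#' @param N Number of consecutive steps the bound must hold for (>= 1).
#' @return Minimum safe step depth in metres. Vectorised.
#' @export
sdp_lower_bound <- function(pfc, eta, dcom, N) {
  if (any(N < 1)) stop("'N' must be >= 1")
  (pfc + eta + (N - 1) * dcom) / N
}

#' Maximum workable step depth for an N-step flight
#'
#' Excessively deep treads defeat the step-by-step strategy: after `N` steps
#' the CoP must have cleared the `(N - 1)`th tread, i.e.
#' `(N - 1) * d <= pfc + L + N * dcom`, giving the upper design bound
#' `d <= (pfc + L + N * dcom) / (N - 1)`.
#'
#' @inheritParams sdp_lower_bound
#' @param L Foot length in m.
#' @param N Number of consecutive steps (>= 2).
#' @return Maximum workable step depth in metres. Vectorised.
#' @export
sdp_upper_bound <- function(pfc, L, dcom, N) {
  if (any(N < 2)) stop("'N' must be >= 2 for the upper bound")
  (pfc + L + N * dcom) / (N - 1)
}

#' Closed-form design range of step depth
#'
#' Combines [sdp_lower_bound()] and [sdp_upper_bound()] at a single set of
#' model parameters and a single flight length.
#'
#' @param params A [model_params()] object.
#' @param N Number of consecutive steps (>= 2).
#' @return Named numeric vector `c(lower, upper)` in metres.
#' @examples
#' sdp_range(model_params(), N = 12)
#' @export
sdp_range <- function(params, N) {
  params <- as_model_params(params)
  dcom <- delta_com(params$v, params$l, params$g)
  lower <- sdp_lower_bound(params$pfc, params$eta, dcom, N)
  upper <- sdp_upper_bound(params$pfc, params$L, dcom, N)
  if (any(lower >= upper)) {
    stop("infeasible parameters: lower bound ", format(lower),
         " is not below upper bound ", format(upper))
  }
  c(lower = lower, upper = upper)
}

#' Step-by-step descent simulation (discrete stability oracle)
#'
#' Walks the flight one step at a time, accumulating the CoP position in the
#' cumulative frame (origin at the first riser, anterior positive). The CoP
#' starts at `pfc + eta` and advances by one CoM drift per step. Step `k` is
#' flagged `risky` when the cumulative CoP position exceeds the anterior edge
#' of the kth tread (`k * d`), and `over_reach` when the (k-1)th tread edge
#' already exceeds the farthest reachable CoP (`pfc + L + k * dcom`).
#' Equality is safe, matching the closed-form inequalities.
#'
#' @param params A [model_params()] object.
#' @param staircase A [staircase_spec()] object.
#' @return A data.frame with one row per step: `step_index`, `cop_position`
#'   (cumulative, m), `bos_edge` (cumulative anterior tread edge, m),
#'   `margin` (edge minus CoP, m; negative flags risk), `risky`,
#'   `over_reach`.
#' @export
simulate_descent <- function(params, staircase) {
  params <- as_model_params(params)
  staircase <- as_staircase_spec(staircase)
  d <- staircase$step_depth
  n <- staircase$n_steps
  dcom <- delta_com(params$v, params$l, params$g)
  cop <- numeric(n)
  pos <- params$pfc + params$eta
  for (k in seq_len(n)) {
    cop[k] <- pos
    pos <- pos + dcom  # iterative accumulation: independent of the algebra
  }
  edge <- seq_len(n) * d
  risky <- cop > edge
  reach <- params$pfc + params$L + seq_len(n) * dcom
  over_reach <- (seq_len(n) - 1) * d > reach
  data.frame(
    step_index = seq_len(n),
    cop_position = cop,
    bos_edge = edge,
    margin = edge - cop,
    risky = risky,
    over_reach = over_reach
  )
}

#' Audit a staircase against the step-depth design bounds
#'
#' Evaluates the closed-form design range over a set of flight lengths and
#' reports whether the staircase's step depth is safe for every one of them.
#' The overall range is the intersection over `N_range`:
#' `[max_N lower(N), min_N upper(N)]`.
#'
#' @param staircase A [staircase_spec()] object.
#' @param params A [model_params()] object.
#' @param N_range Integer vector of consecutive-step counts, each within
#'   `[2, n_steps]`. Default `7:12`.
#' @return An object of class `"staircase_audit"`: a list with `staircase`,
#'   `params`, `per_N` (data.frame of N, lower, upper, safe, violation),
#'   `d_low`, `d_high`, `safe`.
#' @export
audit_staircase <- function(staircase, params, N_range = 7:12) {
  staircase <- as_staircase_spec(staircase)
  params <- as_model_params(params)
  if (length(N_range) == 0) stop("'N_range' must be non-empty")
  N_range <- as.integer(N_range)
  if (any(N_range < 2) || any(N_range > staircase$n_steps)) {
    stop("'N_range' must lie within [2, n_steps]")
  }
  dcom <- delta_com(params$v, params$l, params$g)
  lower <- sdp_lower_bound(params$pfc, params$eta, dcom, N_range)
  upper <- sdp_upper_bound(params$pfc, params$L, dcom, N_range)
  d <- staircase$step_depth
  violation <- ifelse(d < lower, "below lower bound",
               ifelse(d > upper, "above upper bound", ""))
  per_N <- data.frame(
    N = N_range, lower = lower, upper = upper,
    safe = d >= lower & d <= upper, violation = violation,
    stringsAsFactors = FALSE
  )
  out <- list(
    staircase = staircase,
    params = params,
    per_N = per_N,
    d_low = max(lower),
    d_high = min(upper),
    safe = all(per_N$safe)
  )
  class(out) <- "staircase_audit"
  out
}

#' @export
print.staircase_audit <- function(x, ...) {
  cat("Staircase audit:", x$staircase$name, "\n")
  cat(sprintf("  step depth d = %.3f m, %d steps\n",
              x$staircase$step_depth, x$staircase$n_steps))
  cat(sprintf("  required range over N = {%s}: [%.3f, %.3f] m\n",
              paste(x$per_N$N, collapse = ","), x$d_low, x$d_high))
  cat("  verdict:", if (x$safe) "SAFE" else "UNSAFE", "\n")
  if (!x$safe) {
    bad <- x$per_N[!x$per_N$safe, ]
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("    N = %d: %s (range [%.3f, %.3f])\n",
                  bad$N[i], bad$violation[i], bad$lower[i], bad$upper[i]))
    }
  }
  invisible(x)
}
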