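#' Inverted-pendulum model parameters
#'
#' The parameter set of the dynamic-stability model. Defaults are the
#' reference sample means for the study cohort of 72 primary-school
#' students: evacuation-scenario descent speed 0.88 m/s, pendulum length
#' 0.81 m, foot length 0.224 m, heel-to-CoP-junction distance 0.11 m,
#' posterior foot clearance 0.08 m, anterior foot clearance fixed at 0.
#'
#' @param v Horizontal CoM speed in m/s.
#' @param l Pendulum length (CoM to ankle centre) in m.
#' @param L Foot length in m.
#' @param eta Heel-to-CoP-junction distance in m; must satisfy
#'   `0 <= eta <= L`.
#' @param pfc Posterior foot clearance in m.
#' @param afc Anterior foot clearance in m (initial-state indicator only;
#'   it does not enter the design bounds). Default 0.
#' @param g Gravity in m/s^2, default 9.81.
#' @return An object of class `"model_params"` (a named list).
#' @examples
#' model_params()
#' model_params(v = 0.91, l = 0.79)
#' @export
model_params <- function(v = 0.88, l = 0.81, L = 0.224, eta = 0.11,
                         pfc = 0.08, afc = 0, g = 9.81) {
  if (v < 0) stop("'v' must be non-negative")
  if (l <= 0) stop("'l' must be positive")
  if (L <= 0) stop("'L' must be positive")
  if (g <= 0) stop("'g' must be positive")
  if (eta < 0 || eta > L) stop("'eta' must lie in [0, L]")
  if (pfc < 0) stop("'pfc' must be non-negative")
  structure(list(v = v, l = l, L = L, eta = eta, pfc = pfc, afc = afc, g = g),
            class = "model_params")
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (is.list(x)) return(do.call(model_params, x[names(x) %in%
    c("v", "l", "L", "eta", "pfc", "afc", "g")]))
  stop("cannot interpret object as model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> v = %.3f m/s, l = %.3f m, L = %.3f m, eta = %.3f m, pfc = %.3f m, afc = %.3f m, g = %.2f\n",
    x$v, x$l, x$L, x$eta, x$pfc, x$afc, x$g))
  invisible(x)
}
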