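#' Staircase geometry specification
#'
#' One flight of stairs: riser height, step depth (the "going"), step width,
#' inclination angle and number of steps. If `incline` is omitted it is
#' computed as `atan(h / d)` in degrees; if supplied it must agree with the
#' geometry to within 0.05 degrees.
#'
#' @param riser_height Riser height h in m.
#' @param step_depth Step depth d in m.
#' @param step_width Step width w in m.
#' @param n_steps Number of steps in the flight (>= 2).
#' @param incline Optional inclination angle in degrees.
#' @param name Optional site label.
#' @return An object of class `"staircase_spec"`.
#' @examples
#' staircase_spec(0.15, 0.28, 1.36, 12, name = "Chengguan")
#' @export
staircase_spec <- function(riser_height, step_depth, step_width, n_steps,
                           incline = NULL, name = "staircase") {
  stopifnot(is.numeric(riser_height), is.numeric(step_depth),
            is.numeric(step_width), length(riser_height) == 1)
  if (riser_height <= 0) stop("'riser_height' must be positive")
  if (step_depth <= 0) stop("'step_depth' must be positive")
  if (step_width <= 0) stop("'step_width' must be positive")
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 2) stop("'n_steps' must be an integer >= 2")
  theta <- atan(riser_height / step_depth) * 180 / pi
  if (!is.null(incline)) {
    if (abs(incline - theta) > 0.05) {
      stop(sprintf(
        "stated incline %.2f deg inconsistent with atan(h/d) = %.2f deg",
        incline, theta))
    }
    theta <- incline
  }
  structure(
    list(name = name, riser_height = riser_height, step_depth = step_depth,
         step_width = step_width, incline = theta, n_steps = n_steps),
    class = "staircase_spec"
  )
}

as_staircase_spec <- function(x) {
  if (inherits(x, "staircase_spec")) return(x)
  if (is.list(x) && all(c("riser_height", "step_depth", "n_steps") %in% names(x))) {
    return(staircase_spec(x$riser_height, x$step_depth,
                          if (is.null(x$step_width)) 1 else x$step_width,
                          x$n_steps, incline = x$incline,
                          name = if (is.null(x$name)) "staircase" else x$name))
  }
  stop("cannot interpret object as a staircase_spec")
}

#' @export
print.staircase_spec <- function(x, ...) {
  cat(sprintf("<staircase_spec> %s: h = %.3f m, d = %.3f m, w = %.2f m, %.2f deg, %d steps\n",
              x$name, x$riser_height, x$step_depth, x$step_width,
              x$incline, x$n_steps))
  invisible(x)
}

#' Survey geometry of the three experiment-site staircases
#'
#' The measured flights at the three primary schools where the descent
#' trials were run: 0.15 m risers throughout, goings of 0.30, 0.29 and
#' 0.28 m, and 12-step flights. The inclination angle is recomputed from
#' `atan(h/d)` on construction.
#'
#' @return A list of three [staircase_spec()] objects, named by site.
#' @export
experiment_staircases <- function() {
  list(
    Gugua     = staircase_spec(0.15, 0.30, 1.60, 12, name = "Gugua"),
    Zhongle   = staircase_spec(0.15, 0.29, 1.45, 12, name = "Zhongle"),
    Chengguan = staircase_spec(0.15, 0.28, 1.36, 12, name = "Chengguan")
  )
}

#' Convert staircases to / from tabular form
#'
#' @param staircases A list of [staircase_spec()] objects.
#' @return `staircases_to_df()`: a data.frame with one row per flight.
#' @export
staircases_to_df <- function(staircases) {
  if (inherits(staircases, "staircase_spec")) staircases <- list(staircases)
  do.call(rbind, lapply(staircases, function(s) {
    data.frame(name = s$name, riser_height_m = s$riser_height,
               step_depth_m = s$step_depth, step_width_m = s$step_width,
               incline_deg = s$incline, n_steps = s$n_steps,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname staircases_to_df
#' @param df A data.frame in the schema written by [staircases_to_df()].
#' @return `staircases_from_df()`: a named list of [staircase_spec()] objects.
#' @export
staircases_from_df <- function(df) {
  needed <- c("name", "riser_height_m", "step_depth_m", "step_width_m", "n_steps")
  missing <- setdiff(needed, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    staircase_spec(df$riser_height_m[i], df$step_depth_m[i],
                   df$step_width_m[i], df$n_steps[i], name = df$name[i])
  })
  names(out) <- df$name
  out
}
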