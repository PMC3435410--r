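# Dose x dosing-interval response surface: end-of-treatment prostate mass
# over a grid of regimens.

#' Dose-frequency response surface
#'
#' Simulates a 21-day regimen for every combination of dose and dosing
#' interval and records total prostate mass at the end of the dosing window.
#' The default grid spans 0.001 to 1000 mg/kg in half-log steps (13 doses)
#' and 6 to 120 h intervals in 6 h steps (20 intervals). Cells are
#' independent: results do not depend on evaluation order, and a solver
#' failure flags only its own cell (NA) without affecting the rest.
#'
#' @param p parameter set
#' @param doses dose vector, mg/kg (0 allowed: no-drug control)
#' @param intervals dosing intervals, hours
#' @param duration_days length of the dosing window
#' @param dt_out output grid within each simulation, hours
#' @return object of class \code{prostasim_surface}: list with \code{doses},
#'   \code{intervals} and matrix \code{V_end} (doses x intervals, mg)
#' @export
dose_frequency_surface <- function(p = prostasim_params(),
                                   doses = 10^seq(-3, 3, by = 0.5),
                                   intervals = seq(6, 120, by = 6),
                                   duration_days = 21, dt_out = 6) {
  if (!length(doses) || !length(intervals)) stop("doses and intervals must be nonempty")
  if (any(doses < 0) || any(intervals <= 0)) stop("doses must be >= 0 and intervals > 0")
  x0 <- steady_state(p)$state
  t_end <- duration_days * 24
  V <- matrix(NA_real_, length(doses), length(intervals),
              dimnames = list(dose = signif(doses, 4),
                              interval_hr = intervals))
  for (i in seq_along(doses)) for (j in seq_along(intervals)) {
    sim <- tryCatch(
      simulate_scenario(scenario_treated(doses[i], intervals[j], duration_days),
                        p, t_end_hr = t_end, dt_out = dt_out, init_state = x0),
      error = function(e) { warning(sprintf("cell (%g mg/kg, %g h) failed: %s",
                                            doses[i], intervals[j],
                                            conditionMessage(e))); NULL })
    if (!is.null(sim))
      V[i, j] <- sim$observables$V_p[length(sim$time_hr)]
  }
  structure(list(doses = doses, intervals = intervals, V_end = V,
                 duration_days = duration_days),
            class = "prostasim_surface")
}

#' @export
print.prostasim_surface <- function(x, ...) {
  cat("<prostasim_surface>", length(x$doses), "doses x",
      length(x$intervals), "intervals,", x$duration_days, "day regimens\n")
  cat(sprintf("  V_end range: %.1f - %.1f mg (%d failed cells)\n",
              min(x$V_end, na.rm = TRUE), max(x$V_end, na.rm = TRUE),
              sum(is.na(x$V_end))))
  invisible(x)
}

#' @export
as.data.frame.prostasim_surface <- function(x, ...) {
  data.frame(dose = rep(x$doses, times = length(x$intervals)),
             interval_hr = rep(x$intervals, each = length(x$doses)),
             V_end_mg = as.vector(x$V_end))
}

#' @export
plot.prostasim_surface <- function(x, ...) {
  graphics::filled.contour(log10(x$doses), x$intervals, x$V_end,
                           xlab = "log10 dose (mg/kg)",
                           ylab = "dosing interval (h)",
                           main = "Prostate mass at end of dosing (mg)", ...)
  invisible(x)
}
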