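# Scenario definitions: intact, castration, or oral finasteride regimen.

#' Study scenarios
#'
#' \code{scenario_intact()} leaves the system at its hormonal steady state.
#' \code{scenario_castration()} sets testicular T production to zero from
#' \code{castration_time_hr} on. \code{scenario_treated()} administers
#' repeated oral finasteride boluses: \code{dose} mg/kg every
#' \code{interval_hr} hours over \code{duration_days} days of dosing (first
#' dose at t = 0, last dose strictly before the end of the dosing window),
#' followed by \code{washout_days} drug-free days.
#'
#' @param castration_time_hr time of castration, hours
#' @param dose dose per administration, mg/kg
#' @param interval_hr dosing interval, hours
#' @param duration_days length of the dosing window, days
#' @param washout_days drug-free follow-up, days
#' @param n_doses optional explicit number of doses (overrides
#'   \code{duration_days} for the schedule; the dosing window is still
#'   \code{duration_days} long for output purposes)
#' @return a \code{prostasim_scenario} object
#' @export
scenario_intact <- function() {
  structure(list(type = "intact", t_end_hr = 21 * 24),
            class = "prostasim_scenario")
}

#' @rdname scenario_intact
#' @export
scenario_castration <- function(castration_time_hr = 0) {
  if (castration_time_hr < 0) stop("castration_time_hr must be >= 0")
  structure(list(type = "castration", castration_time_hr = castration_time_hr,
                 t_end_hr = 21 * 24),
            class = "prostasim_scenario")
}

#' @rdname scenario_intact
#' @export
scenario_treated <- function(dose = 40, interval_hr = 24, duration_days = 21,
                             washout_days = 0, n_doses = NULL) {
  if (dose < 0) stop("dose must be >= 0")
  if (interval_hr <= 0) stop("interval_hr must be > 0")
  if (duration_days <= 0) stop("duration_days must be > 0")
  if (washout_days < 0) stop("washout_days must be >= 0")
  dosing_end <- duration_days * 24
  n <- if (!is.null(n_doses)) n_doses
       else ceiling(dosing_end / interval_hr - 1e-9)  # last dose < dosing_end
  times <- (seq_len(n) - 1L) * interval_hr
  structure(list(type = "treated", dose = dose, interval_hr = interval_hr,
                 duration_days = duration_days, washout_days = washout_days,
                 dose_times_hr = times,
                 t_end_hr = dosing_end + washout_days * 24),
            class = "prostasim_scenario")
}

#' @export
print.prostasim_scenario <- function(x, ...) {
  cat("<prostasim_scenario>", x$type, "\n")
  if (x$type == "castration")
    cat("  castration at t =", x$castration_time_hr, "h\n")
  if (x$type == "treated")
    cat(sprintf("  %g mg/kg every %g h; %d doses over %g days; washout %g days\n",
                x$dose, x$interval_hr, length(x$dose_times_hr),
                x$duration_days, x$washout_days))
  invisible(x)
}
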