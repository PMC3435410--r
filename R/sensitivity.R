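# Control-coefficient sensitivity analysis and the normalized androgen
# signal used to interpret dose-frequency effects.

.perturbable <- function() setdiff(names(prostasim_defaults()), "w_TD")

# perturbed copy of p with the structural identities re-derived (k2 = Km*k1 -
# kcat, k4 = Ki*k3, and the TD-weight fallback); the steady-state-forced
# constants stay at their baseline values so both runs start from the same
# initialization, matching the finite-difference protocol.
.perturb_param <- function(p, name, factor) {
  p2 <- unclass(p)
  p2[[name]] <- p2[[name]] * factor
  p2$k2 <- derive_k2(p2$Km, p2$k1, p2$kcat)
  p2$k4 <- derive_k4(p2$Ki_5aR2, p2$k3)
  p2$w_TD_eff <- if (is.na(p2$w_TD)) 1 / sqrt(p2$k_DNAoffTT) else p2$w_TD
  class(p2) <- "prostasim_params"
  p2
}

.observable_value <- function(sim, observable, t_hr) {
  i <- which.min(abs(sim$time_hr - t_hr))
  if (is.function(observable)) return(observable(sim))
  if (observable %in% names(sim$observables))
    return(sim$observables[[observable]][i])
  if (observable %in% colnames(sim$states))
    return(sim$states[i, observable])
  stop("unknown observable: ", observable)
}

#' Forward-difference control coefficient
#'
#' Normalized sensitivity of an end-of-regimen observable to a parameter,
#' \code{CCA = [(x(1.01 p) - x(p)) / x(p)] / 0.01}: both runs start from the
#' same (baseline) steady-state initialization and simulate the same
#' regimen; the observable is sampled at the end of the dosing window
#' (pre-dose). The structural identities (\code{k2}, \code{k4}) follow the
#' perturbed parameter; the steady-state-forced constants do not.
#'
#' @param param name of a primary parameter
#' @param observable observable/state column name (e.g. \code{"CD_pf"},
#'   \code{"V_p"}, \code{"CT_bl"}, \code{"DNAo_cd"}) or a function of the
#'   simulation object
#' @param p baseline parameter set
#' @param regimen scenario to run (default 40 mg/kg QD for 21 days)
#' @param delta relative perturbation (default +1\%)
#' @param baseline optional precomputed baseline simulation (shared across
#'   calls by \code{\link{sensitivity_report}})
#' @param dt_out output grid, hours
#' @return the control coefficient (dimensionless scalar)
#' @export
control_coefficient <- function(param, observable = "CD_pf",
                                p = prostasim_params(),
                                regimen = scenario_treated(40, 24, 21),
                                delta = 0.01, baseline = NULL, dt_out = 1) {
  if (!param %in% .perturbable()) stop("unknown parameter: ", param)
  x0 <- steady_state(p)$state
  t_sample <- regimen$t_end_hr
  if (is.null(baseline))
    baseline <- simulate_scenario(regimen, p, init_state = x0, dt_out = dt_out)
  xb <- .observable_value(baseline, observable, t_sample)
  if (!is.finite(xb) || xb == 0)
    stop("observable '", if (is.character(observable)) observable else "<fn>",
         "' is zero or non-finite at the sampling time; control coefficient undefined")
  if (p[[param]] == 0) return(0)  # 1% of zero perturbs nothing
  p2 <- .perturb_param(p, param, 1 + delta)
  pert <- simulate_scenario(regimen, p2, init_state = x0, dt_out = dt_out)
  xp <- .observable_value(pert, observable, t_sample)
  ((xp - xb) / xb) / delta
}

#' Control-coefficient report over parameter/observable pairs
#'
#' Computes forward-difference control coefficients for every requested
#' (parameter, observable) pair, sharing one baseline simulation.
#'
#' @param parameters character vector of parameter names
#' @param observables character vector of observable names
#' @param p parameter set
#' @param regimen scenario (default 21-day 40 mg/kg QD)
#' @param delta relative perturbation
#' @return object of class \code{prostasim_sens}: data.frame with columns
#'   \code{parameter}, \code{observable}, \code{CCA}, plus regimen/delta
#'   attributes
#' @export
sensitivity_report <- function(parameters, observables = "CD_pf",
                               p = prostasim_params(),
                               regimen = scenario_treated(40, 24, 21),
                               delta = 0.01) {
  x0 <- steady_state(p)$state
  baseline <- simulate_scenario(regimen, p, init_state = x0, dt_out = 1)
  rows <- list()
  for (prm in parameters) {
    sims <- if (p[[prm]] == 0) NULL else {
      p2 <- .perturb_param(p, prm, 1 + delta)
      simulate_scenario(regimen, p2, init_state = x0, dt_out = 1)
    }
    for (ob in observables) {
      xb <- .observable_value(baseline, ob, regimen$t_end_hr)
      cca <- if (is.null(sims)) 0
             else ((.observable_value(sims, ob, regimen$t_end_hr) - xb) / xb) / delta
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = prm, observable = ob, CCA = cca)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "regimen") <- regimen
  attr(out, "delta") <- delta
  class(out) <- c("prostasim_sens", "data.frame")
  out
}

#' @export
print.prostasim_sens <- function(x, ...) {
  cat("Control coefficients (forward difference, +",
      100 * attr(x, "delta"), "%):\n", sep = "")
  print.data.frame(transform(x, CCA = signif(CCA, 3)), row.names = FALSE)
  invisible(x)
}

#' Affinity-normalized total androgen signal
#'
#' Prostatic T and DHT trajectories normalized by their AR dissociation
#' constants and summed: \code{signal(t) = CT_pf(t)/KdT + CD_pf(t)/KdD}.
#' This is the comparative "signal strength" used to interpret why some
#' dosing frequencies regress the prostate more than others.
#'
#' @param sim a \code{prostasim_sim} (or list with \code{time_hr},
#'   \code{observables$CT_pf}, \code{observables$CD_pf})
#' @param p parameter set (KdT = koffT/konT, KdD = koffD/konD)
#' @param window time window (hours) for the reported mean; default the last
#'   4 days of the simulation
#' @return list with \code{time_hr}, \code{signal}, \code{mean} (over the
#'   window) and the window used
#' @export
normalized_signal <- function(sim, p = sim$params,
                              window = NULL) {
  KdT <- p$koffT / p$konT
  KdD <- p$koffD / p$konD
  sig <- sim$observables$CT_pf / KdT + sim$observables$CD_pf / KdD
  tmax <- max(sim$time_hr)
  if (is.null(window)) window <- c(tmax - 96, tmax)
  w <- sim$time_hr >= window[1] & sim$time_hr <= window[2]
  list(time_hr = sim$time_hr, signal = sig,
       mean = mean(sig[w]), window = window)
}
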