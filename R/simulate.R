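# Stiff integration with dosing events (bolus additions to the gut depot at
# integrator restarts) and result container. The derivative is evaluated in
# compiled code (src/prostasim_deriv.c) when the package DLL is loaded, with
# the R implementation in model_derivative() as the reference fallback; a
# test asserts their agreement.

# parameter order contract with src/prostasim_deriv.c
.c_param_order <- c(
  "fu", "Vc", "VPC_2", "VPL_2", "V_p0", "Qp0", "V_bl", "V_l",
  "PT_l", "PD_l", "PT_p", "PD_p", "PT_bd", "PD_bd", "V_bd",
  "Q_l", "Q_bd", "V_maxl", "K_m5a", "Ki_5aR1", "k_lT", "k_lD",
  "kdim", "w_TD_eff", "k_DNAoffTT",
  "K_occ_cp", "K_occ_cd", "K_occ_sec", "K_occ_5aR2",
  "k_cp1", "k_cd1", "k_sec", "k_lum",
  "k_dg", "E_free0", "DNAo_5aR20",
  "k1", "k2", "kcat", "k3", "k4", "k5", "k6",
  "konT", "koffT", "konD", "koffD", "kAR_syn", "kAR_deg",
  "kT_prod", "kLH_prod", "kLH_deg", "K_inh", "n_LH", "w_DHT_fb",
  "k_elT_bl", "k_elD_bl",
  "ka", "k10", "k12", "k21"
)

.c_parms <- function(p, scenario) {
  v <- vapply(.c_param_order, function(nm) p[[nm]], numeric(1))
  ct <- if (scenario$type == "castration") scenario$castration_time_hr else Inf
  c(v, castration_time = ct)
}

.compiled_available <- function() {
  is.loaded("prostasim_derivs", PACKAGE = "prostasim")
}

#' Simulate a scenario
#'
#' Integrates the full system with a stiff solver (deSolve, \code{lsoda}) at
#' the default tolerances rtol = 1e-4, atol = 1e-6. Oral doses are applied as
#' bolus additions to the gut depot at event times, which restart the
#' integrator for bit-exact bolus handling. The run starts from the intact
#' steady state unless \code{init_state} is supplied.
#'
#' @param scenario a \code{prostasim_scenario}
#' @param p parameter set
#' @param t_end_hr end of the simulation, hours (default: the scenario's
#'   natural horizon, e.g. dosing window plus washout)
#' @param dt_out output grid spacing, hours
#' @param rtol,atol integrator tolerances
#' @param init_state optional starting state (named vector)
#' @param method deSolve method (default \code{"lsoda"})
#' @param compiled use the compiled derivative (default: automatically when
#'   the package DLL is loaded; \code{FALSE} forces the R implementation)
#' @return object of class \code{prostasim_sim}: list with \code{time_hr},
#'   \code{states} (matrix, columns per \code{\link{state_names}}),
#'   \code{observables} (data.frame of derived quantities), \code{scenario},
#'   \code{params}, \code{solver}
#' @examples
#' \donttest{
#' sim <- simulate_scenario(scenario_castration(), t_end_hr = 240)
#' summary(sim)
#' }
#' @export
simulate_scenario <- function(scenario, p = prostasim_params(),
                              t_end_hr = NULL, dt_out = 1,
                              rtol = 1e-4, atol = 1e-6,
                              init_state = NULL, method = "lsoda",
                              compiled = NULL) {
  stopifnot(inherits(scenario, "prostasim_scenario"))
  if (!inherits(p, "prostasim_params")) p <- validate_params(derive_constants(p))
  if (is.null(t_end_hr)) t_end_hr <- scenario$t_end_hr
  if (t_end_hr <= 0) stop("t_end_hr must be positive")
  y0 <- if (is.null(init_state)) steady_state(p)$state else {
    if (is.null(names(init_state)) || !identical(names(init_state), .state_names))
      stop("init_state must be a named vector in canonical state order")
    init_state
  }

  times <- seq(0, t_end_hr, by = dt_out)
  if (times[length(times)] < t_end_hr) times <- c(times, t_end_hr)
  events <- NULL
  if (scenario$type == "treated" && scenario$dose > 0) {
    amt <- dose_to_nmol(scenario$dose, p$BW, p$MW_F)
    dt_times <- scenario$dose_times_hr
    dt_times <- dt_times[dt_times <= t_end_hr]
    if (length(dt_times) && dt_times[1] == 0) {       # first dose directly
      y0[["A1_f"]] <- y0[["A1_f"]] + amt
      dt_times <- dt_times[-1]
    }
    if (length(dt_times)) {
      times <- sort(unique(c(times, dt_times)))
      events <- list(data = data.frame(var = "A1_f", time = dt_times,
                                       value = amt, method = "add"))
    }
  }

  if (is.null(compiled)) compiled <- .compiled_available()
  out <- if (compiled) {
    deSolve::ode(y = y0, times = times, func = "prostasim_derivs",
                 parms = .c_parms(p, scenario), dllname = "prostasim",
                 initfunc = "prostasim_initmod",
                 method = method, rtol = rtol, atol = atol,
                 events = events, maxsteps = 100000)
  } else {
    deSolve::ode(y = y0, times = times, func = .deriv_desolve,
                 parms = list(p = p, scenario = scenario),
                 method = method, rtol = rtol, atol = atol,
                 events = events, maxsteps = 100000)
  }
  st <- attr(out, "istate")
  if (!is.null(st) && st[1] < 0) stop("solver failure (istate ", st[1], ")")
  tm <- out[, 1L]
  states <- out[, .state_names, drop = FALSE]
  if (any(!is.finite(states))) stop("non-finite values in trajectory")
  # clip-free negativity audit
  scale <- pmax(apply(abs(states), 2L, max), 1)
  neg_tol <- 1e-9 * scale + 100 * atol
  mins <- apply(states, 2L, min)
  bad <- which(mins < -neg_tol)
  if (length(bad))
    stop("negative state beyond tolerance: ",
         paste(sprintf("%s (min %.3g)", colnames(states)[bad], mins[bad]),
               collapse = ", "))
  obs <- derived_observables(states, p)
  structure(list(time_hr = tm, states = states, observables = obs,
                 scenario = scenario, params = p,
                 solver = list(method = method, rtol = rtol, atol = atol,
                               n_steps = if (!is.null(st)) st[3] else NA)),
            class = "prostasim_sim")
}

#' @export
print.prostasim_sim <- function(x, ...) {
  n <- length(x$time_hr)
  cat("<prostasim_sim>", x$scenario$type, "scenario,",
      sprintf("%g h (%d output points)\n", x$time_hr[n], n))
  cat(sprintf("  prostate mass: %.1f -> %.1f mg (%+.1f%%)\n",
              x$observables$V_p[1], x$observables$V_p[n],
              100 * (x$observables$V_p[n] / x$observables$V_p[1] - 1)))
  invisible(x)
}

#' @export
summary.prostasim_sim <- function(object, ...) {
  n <- length(object$time_hr)
  ob <- object$observables
  out <- list(
    scenario = object$scenario$type,
    t_end_hr = object$time_hr[n],
    mass_initial_mg = ob$V_p[1],
    mass_final_mg = ob$V_p[n],
    mass_change_pct = 100 * (ob$V_p[n] / ob$V_p[1] - 1),
    CT_pf_final_nM = ob$CT_pf[n],
    CD_pf_final_nM = ob$CD_pf[n],
    CT_bl_final_nM = ob$CT_bl[n],
    CD_bl_final_nM = ob$CD_bl[n],
    E_active_final_nM = object$states[n, "E"] + object$states[n, "ET"],
    DNAo_cd_final = ob$DNAo_cd[n]
  )
  class(out) <- "summary.prostasim_sim"
  out
}

#' @export
print.summary.prostasim_sim <- function(x, ...) {
  cat("Scenario:", x$scenario, "  horizon:", x$t_end_hr, "h\n")
  cat(sprintf("Prostate mass   %8.1f -> %8.1f mg  (%+.1f%%)\n",
              x$mass_initial_mg, x$mass_final_mg, x$mass_change_pct))
  cat(sprintf("Prostatic T     %8.4f nM   Prostatic DHT %8.4f nM (final, free)\n",
              x$CT_pf_final_nM, x$CD_pf_final_nM))
  cat(sprintf("Blood T         %8.3f nM   Blood DHT     %8.4f nM (final)\n",
              x$CT_bl_final_nM, x$CD_bl_final_nM))
  cat(sprintf("Active 5aR2     %8.3f nM   DNAo_cd       %8.3f (final)\n",
              x$E_active_final_nM, x$DNAo_cd_final))
  invisible(x)
}

#' @export
as.data.frame.prostasim_sim <- function(x, ...) {
  obs <- x$observables
  names(obs) <- paste0("obs_", names(obs))
  cbind(data.frame(time_hr = x$time_hr), as.data.frame(x$states), obs)
}

#' @export
plot.prostasim_sim <- function(x, which = c("mass", "androgens", "occupancy", "drug"),
                               ...) {
  which <- match.arg(which, several.ok = TRUE)
  ob <- x$observables
  tday <- x$time_hr / 24
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  if ("mass" %in% which)
    graphics::plot(tday, ob$V_p, type = "l", xlab = "time (days)",
                   ylab = "prostate mass (mg)", main = "Total prostate mass")
  if ("androgens" %in% which) {
    graphics::matplot(tday, cbind(ob$CT_pf, ob$CD_pf), type = "l", lty = 1,
                      col = c("steelblue", "firebrick"), xlab = "time (days)",
                      ylab = "free conc (nM)", main = "Prostatic androgens")
    graphics::legend("topright", c("T", "DHT"), lty = 1,
                     col = c("steelblue", "firebrick"), bty = "n")
  }
  if ("occupancy" %in% which) {
    graphics::matplot(tday, cbind(ob$DNAo_cp, ob$DNAo_cd, ob$DNAo_sec, ob$DNAo_5aR2),
                      type = "l", lty = 1:4, col = 1, ylim = c(0, 1),
                      xlab = "time (days)", ylab = "occupancy",
                      main = "Gene occupancies")
    graphics::legend("bottomleft", c("proliferation", "anti-apoptosis",
                                     "fluid", "5aR2"), lty = 1:4, bty = "n")
  }
  if ("drug" %in% which)
    graphics::plot(tday, ob$F_free, type = "l", xlab = "time (days)",
                   ylab = "free finasteride (nM)", main = "Central free drug",
                   log = if (all(ob$F_free <= 0)) "" else "")
  invisible(x)
}
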