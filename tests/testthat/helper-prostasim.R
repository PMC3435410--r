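# Shared fixtures: heavy simulations computed once per test run, lazily.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

default_params <- function() cached("params", prostasim_params())

intact_state <- function() cached("x0", steady_state(default_params())$state)

qd_regimen <- function() scenario_treated(40, 24, 21)

# 21-day 40 mg/kg QD treated simulation from the intact steady state
treated_sim <- function() cached("treated", {
  simulate_scenario(qd_regimen(), default_params(),
                    init_state = intact_state(), dt_out = 0.5)
})

# castration over a horizon long enough for terminal regression
castrate_sim <- function() cached("castrate", {
  simulate_scenario(scenario_castration(), default_params(),
                    t_end_hr = 1300, dt_out = 1)
})

# drug-free intact run over the full study window
intact_sim <- function() cached("intact", {
  simulate_scenario(scenario_intact(), default_params(),
                    t_end_hr = 504, dt_out = 1)
})

# value of an observable column at a given hour
obs_at <- function(sim, ob, t_hr) {
  sim$observables[[ob]][which.min(abs(sim$time_hr - t_hr))]
}

# end-of-dosing prostate mass for a 21-day regimen at a given interval
v_end <- function(interval_hr) {
  cached(paste0("v_end_", interval_hr), {
    sim <- simulate_scenario(scenario_treated(40, interval_hr, 21),
                             default_params(), init_state = intact_state(),
                             dt_out = 2)
    sim$observables$V_p[length(sim$time_hr)]
  })
}

# unclassed parameter copy for constructing deliberately modified sets
raw_params <- function(p = default_params()) unclass(p)

reclass <- function(p) { class(p) <- "prostasim_params"; p }
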