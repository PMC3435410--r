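# Whole-system simulation: steady-state persistence, stability, scenarios,
# solver robustness, axis behavior.

test_that("intact scenario holds its steady state for 21 days", {
  sim <- intact_sim()
  x0 <- intact_state()
  nz <- x0 != 0
  drift <- abs(t(sim$states[, nz]) / x0[nz] - 1)
  expect_lt(max(drift), 1e-4)
})

test_that("the intact steady state is locally stable", {
  p <- default_params()
  x0 <- intact_state()
  x1 <- x0 * 1.01
  names(x1) <- names(x0)
  sim <- simulate_scenario(scenario_intact(), p, t_end_hr = 2000,
                           init_state = x1, dt_out = 20)
  last <- sim$states[nrow(sim$states), ]
  nz <- x0 != 0
  expect_lt(max(abs(last[nz] / x0[nz] - 1)), 0.001)
})

test_that("castration regresses the prostate monotonically to its basal mass", {
  sim <- castrate_sim()
  V <- sim$observables$V_p
  expect_equal(V[1], 457)
  expect_true(all(diff(V) < 1e-6))
  expect_equal(V[length(V)], 36.2, tolerance = 0.01)
  # blood T collapses within hours of castration
  expect_lt(obs_at(sim, "CT_bl", 24), 0.05 * 6)
  # LH rises when the androgen signal is lost
  expect_gt(sim$states[nrow(sim$states), "LH"], sim$states[1, "LH"])
})

test_that("21-day daily finasteride regresses less than castration at all times", {
  tr <- treated_sim(); ca <- castrate_sim()
  tt <- tr$time_hr[tr$time_hr <= 504]
  Vtr <- tr$observables$V_p[match(tt, tr$time_hr)]
  Vca <- ca$observables$V_p[match(tt, ca$time_hr)]
  keep <- !is.na(Vca) & tt >= 24
  expect_true(all(Vca[keep] < Vtr[keep]))
})

test_that("treated run reproduces the expected hormone pattern", {
  tr <- treated_sim()
  t <- tr$time_hr; w <- t >= 456 & t <= 504
  p <- default_params()
  # blood DHT down, blood T up, prostatic DHT near-depleted, prostatic T up
  expect_lt(mean(tr$observables$CD_bl[w]), 0.7 * p$CD_bl0)
  expect_gt(mean(tr$observables$CT_bl[w]), 1.1 * p$CT_bl0)
  expect_lt(mean(tr$observables$CD_pf[w]), 0.15 * p$CD_pf0)
  expect_gt(mean(tr$observables$CT_pf[w]), 10 * p$CT_pf0)
})

test_that("blood DHT decline is driven mainly by hepatic 5aR1 inhibition", {
  # disabling only liver inhibition abolishes most of the blood-DHT drop
  # while prostatic DHT still falls far below intact
  p <- default_params()
  pL <- prostasim_params(Ki_5aR1 = 1e9)
  sim <- simulate_scenario(qd_regimen(), pL, dt_out = 1)
  w <- sim$time_hr >= 456 & sim$time_hr <= 504
  cd_bl <- mean(sim$observables$CD_bl[w])
  tr <- treated_sim()
  wt <- tr$time_hr >= 456 & tr$time_hr <= 504
  cd_bl_full <- mean(tr$observables$CD_bl[wt])
  drop_full <- p$CD_bl0 - cd_bl_full
  drop_noliver <- p$CD_bl0 - cd_bl
  expect_lt(drop_noliver, 0.35 * drop_full)
  expect_lt(mean(sim$observables$CD_pf[w]), 0.2 * p$CD_pf0)
})

test_that("a drop in blood DHT at fixed T stimulates LH", {
  p <- default_params()
  expect_equal(lh_derivative(p$LH0, p$CT_bl0, p$CD_bl0, p), 0,
               tolerance = 1e-12)
  expect_gt(lh_derivative(p$LH0, p$CT_bl0, p$CD_bl0 / 2, p), 0)
  expect_lt(lh_derivative(p$LH0, p$CT_bl0, 2 * p$CD_bl0, p), 0)
})

test_that("solver tolerances are converged and runs are deterministic", {
  p <- default_params()
  x0 <- intact_state()
  a <- simulate_scenario(qd_regimen(), p, init_state = x0, dt_out = 4)
  b <- simulate_scenario(qd_regimen(), p, init_state = x0, dt_out = 4)
  expect_identical(a$states, b$states)   # bit-for-bit reproducible
  tight <- simulate_scenario(qd_regimen(), p, init_state = x0, dt_out = 4,
                             rtol = 1e-5, atol = 1e-7)
  v1 <- a$observables$V_p[length(a$time_hr)]
  v2 <- tight$observables$V_p[length(tight$time_hr)]
  expect_lt(abs(v1 - v2) / v2, 0.005)
})

test_that("simulation guards reject invalid inputs", {
  p <- default_params()
  expect_error(simulate_scenario(scenario_intact(), p, t_end_hr = -5),
               "positive")
  bad <- intact_state()[-1]
  expect_error(simulate_scenario(scenario_intact(), p, init_state = bad),
               "canonical")
  expect_error(scenario_treated(dose = -1), "dose")
  expect_error(scenario_treated(interval_hr = 0), "interval")
  expect_error(scenario_castration(-1), ">= 0")
})
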