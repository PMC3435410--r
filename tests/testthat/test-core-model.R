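# Assembled derivative: steady state, mass balance closure, dimensional
# homogeneity, dissipativity, compiled/interpreted agreement.

test_that("intact steady state is an exact fixed point with total mass 457 mg", {
  p <- default_params()
  ss <- steady_state(p)
  expect_lt(ss$residual, 1e-10)
  expect_equal(total_prostate_mass(ss$state, p), 457)
  expect_equal(unname(ss$state[["E"]]), 19)
  expect_equal(unname(ss$state[["ET"]]), 1)
  # additivity of the mass accessor
  st <- ss$state; st[["VPC_1"]] <- st[["VPC_1"]] + 5
  expect_equal(total_prostate_mass(st, p), 462)
  st[["VPC_1"]] <- 0; st[["VPL_1"]] <- 0
  expect_equal(total_prostate_mass(st, p), 36.2)
})

test_that("androgen fluxes close: compartment sums match source/sink totals", {
  p <- default_params()
  ss <- intact_state()
  set.seed(42)
  for (i in 1:100) {
    x <- ss * exp(runif(length(ss), -1, 1))
    names(x) <- names(ss)
    d <- model_derivative(0, x, p, scenario_intact())
    # independent reconstruction of total-T balance from module functions
    V_p <- total_prostate_mass(x, p); V_pL <- V_p * 1e-6
    CT_bl <- x[["AT_bl"]] / p$V_bl; CD_bl <- x[["AD_bl"]] / p$V_bl
    CT_l <- x[["AT_l"]] / (p$V_l * p$PT_l)
    CT_pf <- x[["AT_p"]] / (V_pL * p$PT_p)
    CD_pf <- x[["AD_p"]] / (V_pL * p$PD_p)
    mm <- inhibited_mm_rate(CT_l, 0, p)
    enz <- enzyme_derivatives(x[["E"]], x[["ET"]], x[["EF"]], x[["EFstar"]],
                              CT_pf, 0, 0.9, p)
    rec <- receptor_derivatives(x[["AR"]], x[["ART"]], x[["ARD"]], CT_pf, CD_pf, p)
    dTotT <- p$kT_prod * x[["LH"]] - mm - p$k_lT * p$V_l * CT_l -
      p$k_elT_bl * p$V_bl * CT_bl - (enz$T_consumption + rec$T_net) * V_pL
    sumT <- d[["AT_l"]] + d[["AT_bl"]] + d[["AT_bd"]] + d[["AT_p"]]
    expect_equal(sumT, unname(dTotT), tolerance = 1e-10)
    # DHT: production (liver + prostate) minus eliminations and AR binding
    CD_l <- x[["AD_l"]] / (p$V_l * p$PD_l)
    dTotD <- mm + enz$DHT_production * V_pL - p$k_lD * p$V_l * CD_l -
      p$k_elD_bl * p$V_bl * CD_bl - rec$D_net * V_pL
    sumD <- d[["AD_l"]] + d[["AD_bl"]] + d[["AD_bd"]] + d[["AD_p"]]
    expect_equal(sumD, unname(dTotD), tolerance = 1e-10)
  }
})

test_that("derivative is dimensionally homogeneous in time", {
  # doubling every per-time constant must exactly double the derivative
  rate_names <- c("ka", "k10", "k12", "k21", "Q_l", "Q_bd", "Qp0", "V_maxl",
                  "k_lT", "k_lD", "k1", "k2", "kcat", "k3", "k4", "k5", "k6",
                  "k_dg", "k_cp1", "k_cd1", "k_sec", "k_lum", "konT", "koffT",
                  "konD", "koffD", "kAR_syn", "kAR_deg", "kT_prod",
                  "kLH_prod", "kLH_deg", "k_elT_bl", "k_elD_bl")
  p <- default_params()
  p2 <- raw_params()
  for (nm in rate_names) p2[[nm]] <- p2[[nm]] * 2
  p2 <- reclass(p2)
  set.seed(3)
  ss <- intact_state()
  for (i in 1:20) {
    x <- ss * exp(runif(length(ss), -1, 1)); names(x) <- names(ss)
    expect_equal(model_derivative(0, x, p2, scenario_intact()),
                 2 * model_derivative(0, x, p, scenario_intact()),
                 tolerance = 1e-12)
  }
})

test_that("with sources and sinks disabled, conserved totals are dissipative", {
  # turn off synthesis/production and all eliminations: total androgen in the
  # system must be constant; with eliminations on but production off, totals
  # are non-increasing
  p0 <- raw_params()
  p0$kT_prod <- 0; p0$kAR_syn <- 0
  p0$V_maxl <- 1e-12; p0$k_lT <- 0; p0$k_lD <- 0
  p0$k_elT_bl <- 0; p0$k_elD_bl <- 0
  p0$k_dg <- 1e-12; p0$E_free0 <- 0   # no enzyme synthesis either
  p0 <- reclass(p0)
  x <- intact_state()
  sim <- simulate_scenario(scenario_intact(), p0, t_end_hr = 100,
                           init_state = x, dt_out = 10, rtol = 1e-10,
                           atol = 1e-12)
  st <- sim$states
  V_pL <- (st[, "VPC_1"] + st[, "VPL_1"] + p0$VPC_2 + p0$VPL_2) * 1e-6
  totT <- st[, "AT_l"] + st[, "AT_bl"] + st[, "AT_bd"] + st[, "AT_p"] +
    (st[, "ET"] + st[, "ART"]) * V_pL
  totD <- st[, "AD_l"] + st[, "AD_bl"] + st[, "AD_bd"] + st[, "AD_p"] +
    st[, "ARD"] * V_pL
  # T is conserved up to conversion into DHT; T+DHT is conserved exactly
  tot <- totT + totD
  expect_lt(max(abs(tot / tot[1] - 1)), 1e-6)
  # T alone can only decrease (one-way conversion to DHT)
  expect_true(all(diff(totT) <= 1e-9 * totT[1]))
})

test_that("compiled and interpreted derivatives agree to machine precision", {
  p <- default_params()
  ss <- intact_state()
  set.seed(11)
  for (sc in list(scenario_intact(), scenario_castration(5))) {
    for (i in 1:25) {
      x <- ss * exp(runif(length(ss), -1, 1)); names(x) <- names(ss)
      x[["A1_f"]] <- runif(1, 0, 1e4); x[["A2_f"]] <- runif(1, 0, 5e3)
      dR <- model_derivative(8, x, p, sc)
      dC <- deSolve::DLLfunc(y = x, times = 8, func = "prostasim_derivs",
                             dllname = "prostasim",
                             initfunc = "prostasim_initmod",
                             parms = prostasim:::.c_parms(p, sc))$dy
      expect_equal(unname(dC), unname(dR), tolerance = 1e-13)
    }
  }
})

test_that("state vector layout is frozen and serialization round-trips", {
  expect_identical(state_names()[1:3], c("A1_f", "A2_f", "A3_f"))
  expect_length(state_names(), 21)
  x <- intact_state()
  expect_identical(names(x), state_names())
  rt <- unlist(as.list(x))
  expect_identical(rt, x)
  # trajectory CSV round trip preserves values and column order
  sim <- simulate_scenario(scenario_intact(), default_params(), t_end_hr = 5,
                           dt_out = 1)
  f <- tempfile(fileext = ".csv")
  write_trajectory(sim, f)
  df <- utils::read.csv(f)
  expect_identical(names(df)[1], "time_hr")
  expect_identical(names(df)[2:22], state_names())
  expect_true(all(startsWith(names(df)[23:38], "obs_")))
  expect_equal(df$AT_bl, unname(sim$states[, "AT_bl"]), tolerance = 1e-12)
})

test_that("derivative rejects non-finite states by name", {
  x <- intact_state(); x[["LH"]] <- NaN
  expect_error(model_derivative(0, x, default_params()), "LH")
})
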