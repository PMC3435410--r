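# AR binding, dimer algebra, gene occupancy, finite-site reference solver.

receptor_ode <- function(y0, t_end, CT, CD, p) {
  f <- function(t, y, parms) {
    d <- receptor_derivatives(y[1], y[2], y[3], CT, CD, p)
    list(c(d$dAR, d$dART, d$dARD))
  }
  out <- deSolve::ode(y0, c(0, t_end), f, NULL, rtol = 1e-11, atol = 1e-13)
  out[nrow(out), 2:4]
}

test_that("receptor pools relax to the linear-system equilibrium", {
  p <- default_params()
  # isolated turnover: free AR settles at synthesis/degradation
  eq0 <- receptor_ode(c(1, 0, 0), 400, 0, 0, p)
  expect_equal(unname(eq0[1]), p$kAR_syn / p$kAR_deg, tolerance = 1e-6)
  expect_equal(unname(eq0[2]), 0); expect_equal(unname(eq0[3]), 0)
  # two-ligand equilibrium vs. independent linear-algebra oracle
  set.seed(5)
  for (i in 1:10) {
    CT <- runif(1, 0, 20); CD <- runif(1, 0, 10)
    A <- matrix(c(
      -p$kAR_deg - p$konT * CT - p$konD * CD, p$koffT, p$koffD,
      p$konT * CT, -(p$koffT + p$kAR_deg), 0,
      p$konD * CD, 0, -(p$koffD + p$kAR_deg)), 3, 3, byrow = TRUE)
    oracle <- solve(A, c(-p$kAR_syn, 0, 0))
    eq <- receptor_ode(c(5, 0, 0), 600, CT, CD, p)
    expect_equal(unname(eq), unname(oracle), tolerance = 1e-7)
  }
})

test_that("swapping ligand concentrations and rate pairs swaps the complexes", {
  p <- raw_params()
  psw <- p
  psw$konT <- p$konD; psw$koffT <- p$koffD
  psw$konD <- p$konT; psw$koffD <- p$koffT
  a <- receptor_ode(c(5, 0, 0), 300, 7, 2, reclass(p))
  b <- receptor_ode(c(5, 0, 0), 300, 2, 7, reclass(psw))
  expect_equal(unname(a[2]), unname(b[3]), tolerance = 1e-9)
  expect_equal(unname(a[3]), unname(b[2]), tolerance = 1e-9)
})

test_that("dimer algebra carries the right combinatorics and stays bounded", {
  p <- default_params()
  expect_equal(unname(dimer_concentrations(0, 5, p)),
               c(0, 0, p$kdim * 25))
  dm <- dimer_concentrations(3, 3, p)
  expect_equal(dm[["TT"]], dm[["DD"]])
  expect_equal(dm[["TD"]], 2 * dm[["TT"]])
  # quasi-equilibrium vs a conserving dynamic dimerization oracle
  dyn_eq <- function(ARTt, ARDt, kdim) {
    # fast reversible dimerization with monomer conservation, kr = 1
    f <- function(t, y, parms) {
      a <- ARTt - 2 * y[1] - y[2]; b <- ARDt - 2 * y[3] - y[2]
      list(c(kdim * a^2 - y[1],
             2 * kdim * a * b - y[2],
             kdim * b^2 - y[3]))
    }
    out <- deSolve::ode(c(0, 0, 0), c(0, 500), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
    out[2, 2:4]
  }
  set.seed(9)
  for (i in 1:50) {
    ART <- runif(1, 0, 30); ARD <- runif(1, 0, 30)
    dm <- dimer_concentrations(ART, ARD, p)
    # dimerized monomer equivalents never exceed the supplied monomer
    expect_lte(2 * sum(dm), ART + ARD + 1e-9)
    # and agree with the depletion-aware oracle in the dilute regime
    or <- dyn_eq(ART, ARD, p$kdim)
    expect_equal(unname(dm), unname(or), tolerance = 0.35)
  }
})

test_that("occupancy is a bounded, monotone, scale-invariant isotherm", {
  p <- default_params()
  expect_equal(gene_occupancy(0, 0, 0, "cd", p), 0)
  # half-occupancy when the weighted signal equals the gene constant
  expect_equal(gene_occupancy(0, 0, p$K_occ_cd, "cd", p), 0.5)
  expect_error(gene_occupancy(1, 1, 1, "nope", p), "unknown gene")
  set.seed(13)
  for (i in 1:200) {
    d <- runif(3, 0, 0.2)
    occ <- gene_occupancy(d[1], d[2], d[3], "cp", p)
    expect_gte(occ, 0); expect_lte(occ, 1)
    # strictly increasing in each dimer species
    for (j in 1:3) {
      d2 <- d; d2[j] <- d2[j] + 0.05
      expect_gt(gene_occupancy(d2[1], d2[2], d2[3], "cp", p), occ)
    }
    # joint rescaling of dimers and K_occ leaves occupancy unchanged
    lam <- runif(1, 0.1, 10)
    p2 <- raw_params(); p2$K_occ_cp <- p2$K_occ_cp * lam
    expect_equal(gene_occupancy(lam * d[1], lam * d[2], lam * d[3], "cp",
                                reclass(p2)), occ, tolerance = 1e-12)
  }
  # intact anchor reproduced by the forced constants
  dm0 <- dimer_concentrations(p$ART0, p$ARD0, p)
  expect_equal(gene_occupancy(dm0[["TT"]], dm0[["TD"]], dm0[["DD"]], "5aR2", p),
               0.95, tolerance = 1e-10)
  expect_equal(gene_occupancy(dm0[["TT"]], dm0[["TD"]], dm0[["DD"]], "cd", p),
               p$DNAo_cd0, tolerance = 1e-10)
})

test_that("site depletion is negligible at 40-fold dimer excess", {
  p <- default_params()
  set.seed(17)
  for (i in 1:100) {
    W <- 10^runif(1, -3, 1)
    K <- 10^runif(1, -3, 0)
    free_iso <- (W / K) / (1 + W / K)
    finite <- occupancy_finite_sites(W, K, sites = W / 40)
    expect_lt(abs(finite - free_iso) / free_iso, 0.05)
    # fixed-point oracle for the finite-site equilibrium itself
    occ <- free_iso
    for (it in 1:200) {
      Wf <- W - occ * W / 40
      occ <- (Wf / K) / (1 + Wf / K)
    }
    expect_equal(finite, occ, tolerance = 1e-8)
    # with sites comparable to dimers, depletion must matter
    expect_lt(occupancy_finite_sites(W, K, sites = 5 * W), free_iso)
  }
})
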