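# Full system derivative, assembled from the per-organ module functions.
# Every inter-compartment mass-transfer flux is computed once and applied with
# opposite signs on the two sides, so androgen mass balance closes up to the
# explicit synthesis and elimination terms.

#' Assembled system derivative
#'
#' Concatenates the finasteride PK, liver, blood/body/LH axis, prostatic
#' androgen, 5aR2, AR and prostate-mass contributions into the full
#' 21-dimensional derivative. Concentration-based prostate species (enzyme
#' and receptor pools) carry a dilution term \code{-C * (dV_p/dt)/V_p} so
#' that their amounts are conserved while the prostate changes volume.
#'
#' @param t time, hours
#' @param state named state vector (see \code{\link{state_names}})
#' @param p parameter set from \code{\link{prostasim_params}}
#' @param scenario a \code{prostasim_scenario} (dosing enters via integration
#'   events, not through this function; only castration alters the
#'   derivative itself)
#' @return named vector of derivatives, same order as the state
#' @export
model_derivative <- function(t, state, p, scenario = scenario_intact()) {
  if (any(!is.finite(state)))
    stop("non-finite state entries: ",
         paste(.state_names[!is.finite(state)], collapse = ", "))
  y <- as.numeric(state)
  A1 <- y[1L]; A2 <- y[2L]; A3 <- y[3L]
  AT_l <- y[4L]; AD_l <- y[5L]
  AT_bl <- y[6L]; AD_bl <- y[7L]
  AT_bd <- y[8L]; AD_bd <- y[9L]
  LH <- y[10L]
  AT_p <- y[11L]; AD_p <- y[12L]
  E <- y[13L]; ET <- y[14L]; EF <- y[15L]; EFstar <- y[16L]
  AR <- y[17L]; ART <- y[18L]; ARD <- y[19L]
  VPC_1 <- y[20L]; VPL_1 <- y[21L]

  F_free <- p$fu * A2 / p$Vc
  V_p <- VPC_1 + VPL_1 + p$VPC_2 + p$VPL_2
  V_pL <- V_p * 1e-6
  Q_p <- p$Qp0 * V_p / p$V_p0
  CT_bl <- AT_bl / p$V_bl
  CD_bl <- AD_bl / p$V_bl
  CT_pf <- AT_p / (V_pL * p$PT_p)
  CD_pf <- AD_p / (V_pL * p$PD_p)

  # occupancies (algebraic, quasi-equilibrium dimers)
  TT <- p$kdim * ART^2
  TD <- 2 * p$kdim * ART * ARD
  DD <- p$kdim * ARD^2
  W <- max(DD + p$w_TD_eff * TD + TT / p$k_DNAoffTT, 0)
  occ_of <- function(K) { S <- W / K; S / (1 + S) }
  occ <- list(cp = occ_of(p$K_occ_cp), cd = occ_of(p$K_occ_cd),
              sec = occ_of(p$K_occ_sec), a5 = occ_of(p$K_occ_5aR2))

  # prostate mass first: its rate sets the dilution of concentration species
  dmass <- mass_derivatives(VPC_1, VPL_1, occ, p)
  dil <- (dmass[[1L]] + dmass[[2L]]) / V_p   # 1/hr

  enz <- enzyme_derivatives(E, ET, EF, EFstar, CT_pf, F_free, occ$a5, p)
  rec <- receptor_derivatives(AR, ART, ARD, CT_pf, CD_pf, p)
  liv <- liver_derivatives(AT_l, AD_l, CT_bl, CD_bl, F_free, p)
  pros <- prostate_androgen_derivatives(AT_p, AD_p, CT_bl, CD_bl,
                                        enz, rec, V_p, Q_p, p)

  # lumped body: flow-limited exchange only
  uptake_T_bd <- p$Q_bd * (CT_bl - AT_bd / (p$V_bd * p$PT_bd))
  uptake_D_bd <- p$Q_bd * (CD_bl - AD_bd / (p$V_bd * p$PD_bd))

  # testes: LH-driven T production, removed under castration
  prod_T <- p$kT_prod * LH
  if (scenario$type == "castration" && t >= scenario$castration_time_hr)
    prod_T <- 0

  dpk <- pk_derivative(A1, A2, A3, enz$F_binding * V_pL, p)

  d <- numeric(21L)
  d[1L] <- dpk[[1L]]; d[2L] <- dpk[[2L]]; d[3L] <- dpk[[3L]]
  d[4L] <- liv$dAT_l; d[5L] <- liv$dAD_l
  d[6L] <- prod_T - liv$uptake_T - uptake_T_bd - pros$uptake_T -
    p$k_elT_bl * p$V_bl * CT_bl
  d[7L] <- -liv$uptake_D - uptake_D_bd - pros$uptake_D -
    p$k_elD_bl * p$V_bl * CD_bl
  d[8L] <- uptake_T_bd; d[9L] <- uptake_D_bd
  d[10L] <- lh_derivative(LH, CT_bl, CD_bl, p)
  d[11L] <- pros$dAT_p; d[12L] <- pros$dAD_p
  d[13L] <- enz$dE - dil * E
  d[14L] <- enz$dET - dil * ET
  d[15L] <- enz$dEF - dil * EF
  d[16L] <- enz$dEFstar - dil * EFstar
  d[17L] <- rec$dAR - dil * AR
  d[18L] <- rec$dART - dil * ART
  d[19L] <- rec$dARD - dil * ARD
  d[20L] <- dmass[[1L]]; d[21L] <- dmass[[2L]]
  if (any(!is.finite(d)))
    stop("non-finite derivative for state(s): ",
         paste(.state_names[!is.finite(d)], collapse = ", "))
  names(d) <- .state_names
  d
}

# deSolve-facing wrapper
.deriv_desolve <- function(t, y, parms) {
  list(model_derivative(t, y, parms$p, parms$scenario))
}
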