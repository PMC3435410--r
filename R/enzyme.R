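# Prostatic 5aR2 mass-action kinetics: substrate binding/catalysis, two-step
# time-dependent inhibition by finasteride, occupancy-driven synthesis with
# steady-state forcing. Degradation (k_dg) acts on E, EF and EFstar but not on
# the catalytic complex ET, which keeps the printed steady-state partition
# (free 19 nM, bound 1 nM, synthesis = k_dg * 19) exactly self-consistent and
# lets permanently inhibited enzyme clear after washout.

#' Gene-occupancy-driven 5aR2 synthesis rate
#'
#' Steady-state-forced synthesis: \code{E_syn = k_dg * E_free0 *
#' (DNAo_5aR2 / DNAo_5aR20)}, which equals degradation of the free pool when
#' occupancy sits at its intact anchor.
#'
#' @param DNAo_5aR2 current 5aR2-gene occupancy, fraction in [0, 1]
#' @param p parameter set
#' @return synthesis rate, nM/hr
#' @export
synthesis_rate <- function(DNAo_5aR2, p) {
  if (p$DNAo_5aR20 <= 0) stop("DNAo_5aR20 must be positive")
  p$k_dg * p$E_free0 * (DNAo_5aR2 / p$DNAo_5aR20)
}

#' 5aR2 species derivatives and coupled androgen/drug fluxes
#'
#' Mass-action kinetics of the free enzyme E, the catalytic complex ET, the
#' reversible inhibitor complex EF and the quasi-irreversibly inhibited
#' EFstar. Also returns the concentration-rate fluxes coupled to the
#' prostatic androgen and finasteride balances (multiply by prostate volume
#' in L to convert nM/hr to nmol/hr).
#'
#' @param E,ET,EF,EFstar species concentrations, nM
#' @param CT_pf free prostatic T, nM
#' @param F_free free finasteride, nM
#' @param DNAo_5aR2 5aR2-gene occupancy driving synthesis
#' @param p parameter set
#' @return list with \code{dE, dET, dEF, dEFstar} (nM/hr, before any volume
#'   dilution correction) and the exported fluxes \code{T_consumption}
#'   (\code{k1*CT_pf*E - k2*ET}), \code{DHT_production} (\code{kcat*ET}) and
#'   \code{F_binding} (\code{k3*F_free*E - k4*EF}), all nM/hr
#' @export
enzyme_derivatives <- function(E, ET, EF, EFstar, CT_pf, F_free, DNAo_5aR2, p) {
  E_syn <- synthesis_rate(DNAo_5aR2, p)
  bindT <- p$k1 * CT_pf * E - p$k2 * ET
  bindF <- p$k3 * F_free * E - p$k4 * EF
  cat_rel <- (p$k2 + p$kcat) * ET
  list(
    dE = E_syn - p$k_dg * E - p$k1 * CT_pf * E + cat_rel - bindF,
    dET = p$k1 * CT_pf * E - cat_rel,
    dEF = bindF - p$k5 * EF + p$k6 * EFstar - p$k_dg * EF,
    dEFstar = p$k5 * EF - p$k6 * EFstar - p$k_dg * EFstar,
    T_consumption = bindT,
    DHT_production = p$kcat * ET,
    F_binding = bindF
  )
}
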