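# Hepatic T/DHT mass balances; 5aR1-mediated T -> DHT under competitive,
# reversible finasteride inhibition. 5aR1 activity itself is unregulated
# (constant V_maxl across castration and treatment).

#' Finasteride-inhibited hepatic T metabolism rate
#'
#' Michaelis-Menten conversion of T to DHT by 5aR1 with the Km inflated by
#' the competitive-inhibition factor \code{(1 + F_free/Ki_5aR1)}.
#'
#' @param CT_l free hepatic T concentration, nM
#' @param F_free free finasteride concentration, nM
#' @param p parameter set
#' @return rate in nmol/hr, bounded above by \code{V_maxl}
#' @export
inhibited_mm_rate <- function(CT_l, F_free, p) {
  p$V_maxl * CT_l / (p$K_m5a * (1 + F_free / p$Ki_5aR1) + CT_l)
}

#' Hepatic T and DHT derivatives
#'
#' Flow-limited exchange with blood, 5aR1 metabolism (1:1 stoichiometry,
#' every nmol of T lost appears as DHT), and nonspecific first-order
#' elimination applied to the free hepatic concentrations.
#'
#' @param AT_l,AD_l hepatic amounts, nmol
#' @param CT_bl,CD_bl blood concentrations, nM
#' @param F_free free finasteride, nM
#' @param p parameter set
#' @return list with \code{dAT_l}, \code{dAD_l} (nmol/hr) and the blood->liver
#'   uptake fluxes \code{uptake_T}, \code{uptake_D} (nmol/hr, positive into
#'   the liver) for mass-balance closure in the assembled system
#' @export
liver_derivatives <- function(AT_l, AD_l, CT_bl, CD_bl, F_free, p) {
  CT_l <- AT_l / (p$V_l * p$PT_l)
  CD_l <- AD_l / (p$V_l * p$PD_l)
  mm <- inhibited_mm_rate(CT_l, F_free, p)
  uptake_T <- p$Q_l * (CT_bl - CT_l)
  uptake_D <- p$Q_l * (CD_bl - CD_l)
  list(dAT_l = uptake_T - mm - p$k_lT * p$V_l * CT_l,
       dAD_l = uptake_D + mm - p$k_lD * p$V_l * CD_l,
       uptake_T = uptake_T, uptake_D = uptake_D, mm = mm)
}
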