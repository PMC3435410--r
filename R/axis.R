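# Testicular-pituitary axis and whole-body androgen PBPK pieces: LH feedback,
# testicular T production, flow-limited blood/body exchange, and the prostatic
# androgen balances coupled to the 5aR2 and AR modules.

#' LH derivative under combined androgen feedback
#'
#' Hill-type negative feedback of potency-weighted blood androgen on LH
#' production, \code{dLH = kLH_prod / (1 + (S/K_inh)^n) - kLH_deg * LH} with
#' the sensed signal \code{S = CT_bl + w_DHT_fb * CD_bl}: DHT is weighted by
#' its relative androgenic potency at the hypothalamic-pituitary sensor, so a
#' drop in blood DHT is a strong, fast stimulus for LH even when T is intact.
#' \code{kLH_prod} is steady-state forced so intact LH sits at \code{LH0}.
#'
#' @param LH normalized LH level
#' @param CT_bl,CD_bl blood androgen concentrations, nM
#' @param p parameter set
#' @return dLH/dt (1/hr, normalized units)
#' @export
lh_derivative <- function(LH, CT_bl, CD_bl, p) {
  sensed <- CT_bl + p$w_DHT_fb * CD_bl
  p$kLH_prod / (1 + (sensed / p$K_inh)^p$n_LH) - p$kLH_deg * LH
}

#' Prostatic androgen derivatives
#'
#' Flow-limited exchange with blood plus the enzyme and receptor couplings:
#' T is consumed by net 5aR2 binding and AR binding; DHT is produced by
#' catalysis and consumed by AR binding. Enzyme/receptor fluxes arrive in
#' nM/hr and are converted with the prostate volume (1 mg = 1 uL).
#'
#' @param AT_p,AD_p prostatic amounts, nmol
#' @param CT_bl,CD_bl blood concentrations, nM
#' @param enz list from \code{\link{enzyme_derivatives}}
#' @param rec list from \code{\link{receptor_derivatives}}
#' @param V_p total prostate mass, mg
#' @param Q_p prostatic blood flow, L/hr
#' @param p parameter set
#' @return list with \code{dAT_p}, \code{dAD_p} (nmol/hr) and the blood ->
#'   prostate uptake fluxes \code{uptake_T}, \code{uptake_D} (nmol/hr)
#' @export
prostate_androgen_derivatives <- function(AT_p, AD_p, CT_bl, CD_bl,
                                          enz, rec, V_p, Q_p, p) {
  V_pL <- V_p * 1e-6
  CT_pf <- AT_p / (V_pL * p$PT_p)
  CD_pf <- AD_p / (V_pL * p$PD_p)
  uptake_T <- Q_p * (CT_bl - CT_pf)
  uptake_D <- Q_p * (CD_bl - CD_pf)
  list(
    dAT_p = uptake_T - (enz$T_consumption + rec$T_net) * V_pL,
    dAD_p = uptake_D + (enz$DHT_production - rec$D_net) * V_pL,
    uptake_T = uptake_T, uptake_D = uptake_D
  )
}
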