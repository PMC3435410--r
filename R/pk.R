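# Two-compartment oral finasteride PK with a sink flux for prostatic 5aR2 binding.

#' Oral dose conversion to nmol
#'
#' @param dose_mg_per_kg dose in mg/kg
#' @param BW body weight, kg
#' @param MW molecular weight, g/mol
#' @return amount in nmol
#' @examples
#' dose_to_nmol(40)  # ~37579 nmol for a 0.35 kg rat
#' @export
dose_to_nmol <- function(dose_mg_per_kg, BW = 0.35, MW = 372.55) {
  if (any(dose_mg_per_kg < 0)) stop("dose must be non-negative")
  if (BW <= 0 || MW <= 0) stop("BW and MW must be positive")
  dose_mg_per_kg * BW / MW * 1e6
}

#' Free finasteride concentration in the central compartment
#'
#' Only unbound drug is available to inhibit 5aR; free plasma drug is assumed
#' in equilibrium with free drug in the well-perfused liver and prostate, so
#' this single concentration drives both sites.
#'
#' @param A2 central-compartment amount, nmol
#' @param p parameter set (uses \code{fu}, \code{Vc})
#' @return free concentration in nM
#' @export
free_central_concentration <- function(A2, p) {
  if (p$Vc <= 0) stop("Vc must be positive")
  p$fu * A2 / p$Vc
}

#' Finasteride PK derivatives
#'
#' First-order absorption from the gut depot, linear elimination and
#' peripheral distribution, and a sink on the central compartment for net
#' binding to prostatic 5aR2.
#'
#' @param A1,A2,A3 gut, central and peripheral amounts, nmol
#' @param prostate_binding_flux net binding flux to prostatic 5aR2, nmol/hr
#' @param p parameter set
#' @return named vector \code{c(dA1, dA2, dA3)} in nmol/hr
#' @export
pk_derivative <- function(A1, A2, A3, prostate_binding_flux, p) {
  c(dA1 = -p$ka * A1,
    dA2 = p$ka * A1 - (p$k10 + p$k12) * A2 + p$k21 * A3 - prostate_binding_flux,
    dA3 = p$k12 * A2 - p$k21 * A3)
}
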