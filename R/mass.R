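# Androgen-sensitive prostate mass dynamics driven by gene occupancies, with
# steady-state-forced death/clearance constants (see force_death_constants).

#' Prostate mass derivatives
#'
#' Cellular mass grows with proliferation-gene occupancy and dies at a rate
#' suppressed by anti-apoptotic occupancy,
#' \code{dVPC_1 = k_cp1*DNAo_cp - k_cd1*(1 - DNAo_cd)*VPC_1}; ductal lumen
#' mass balances occupancy-driven fluid production against first-order
#' clearance, \code{dVPL_1 = k_sec*DNAo_sec - k_lum*VPL_1}. No saturating
#' capacity factor on growth.
#'
#' @param VPC_1,VPL_1 androgen-sensitive cellular and lumen mass, mg
#' @param occ named list/vector with occupancies \code{cp}, \code{cd},
#'   \code{sec} (fractions)
#' @param p parameter set
#' @return named vector \code{c(dVPC_1, dVPL_1)} in mg/hr
#' @export
mass_derivatives <- function(VPC_1, VPL_1, occ, p) {
  c(dVPC_1 = p$k_cp1 * occ[["cp"]] - p$k_cd1 * (1 - occ[["cd"]]) * VPC_1,
    dVPL_1 = p$k_sec * occ[["sec"]] - p$k_lum * VPL_1)
}
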