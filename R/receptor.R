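# AR ligand binding (dynamic) and dimerization / DNA occupancy (algebraic,
# quasi-equilibrium). Ligand held in a degraded complex is returned to the
# free androgen pool, so receptor turnover does not silently destroy androgen.

#' Androgen receptor species derivatives
#'
#' Free AR turnover (zeroth-order synthesis, first-order degradation) and
#' reversible binding of free prostatic T and DHT. Liganded complexes degrade
#' at the same first-order rate; their ligand is exported back to the free
#' androgen pool via the net fluxes.
#'
#' @param AR,ART,ARD free and liganded receptor, nM
#' @param CT_pf,CD_pf free prostatic androgens, nM
#' @param p parameter set
#' @return list with \code{dAR, dART, dARD} (nM/hr, before volume dilution)
#'   and net androgen consumption fluxes \code{T_net, D_net} (nM/hr; binding
#'   minus dissociation minus ligand returned on complex degradation)
#' @export
receptor_derivatives <- function(AR, ART, ARD, CT_pf, CD_pf, p) {
  bT <- p$konT * CT_pf * AR - p$koffT * ART
  bD <- p$konD * CD_pf * AR - p$koffD * ARD
  list(
    dAR = p$kAR_syn - p$kAR_deg * AR - bT - bD,
    dART = bT - p$kAR_deg * ART,
    dARD = bD - p$kAR_deg * ARD,
    T_net = bT - p$kAR_deg * ART,
    D_net = bD - p$kAR_deg * ARD
  )
}

#' Quasi-equilibrium dimer concentrations
#'
#' Lowest-order mass-action dimer algebra with a single association constant:
#' \code{TT = kdim*ART^2}, \code{TD = 2*kdim*ART*ARD} (statistical factor 2),
#' \code{DD = kdim*ARD^2}. Valid while the dimerized fraction of the monomer
#' pool is small.
#'
#' @param ART,ARD liganded monomer concentrations, nM
#' @param p parameter set
#' @return named vector \code{c(TT, TD, DD)} in nM
#' @export
dimer_concentrations <- function(ART, ARD, p) {
  c(TT = p$kdim * ART^2,
    TD = 2 * p$kdim * ART * ARD,
    DD = p$kdim * ARD^2)
}

#' Fractional gene occupancy from dimer concentrations
#'
#' Site-depletion-free binding isotherm: the potency-weighted dimer signal
#' \code{W = DD + w_TD*TD + TT/k_DNAoffTT} saturates a gene-specific
#' half-saturation constant, \code{occ = (W/K) / (1 + W/K)}. TT homodimers are
#' discounted by the relative-potency divisor \code{k_DNAoffTT}; the TD weight
#' defaults to the geometric mean \code{1/sqrt(k_DNAoffTT)}.
#'
#' @param TT,TD,DD dimer concentrations, nM
#' @param gene one of \code{"cp"} (proliferation), \code{"cd"}
#'   (anti-apoptosis), \code{"sec"} (fluid production), \code{"5aR2"}
#' @param p parameter set (per-gene \code{K_occ_*} are steady-state forced)
#' @return occupancy fraction in [0, 1]
#' @export
gene_occupancy <- function(TT, TD, DD, gene, p) {
  K <- p[[paste0("K_occ_", gene)]]
  if (is.null(K)) stop("unknown gene id: ", gene)
  S <- pmax(DD + p$w_TD_eff * TD + TT / p$k_DNAoffTT, 0) / K
  S / (1 + S)
}

#' Occupancy of a finite pool of DNA binding sites (reference solver)
#'
#' Solves the single-site binding equilibrium with explicit site depletion:
#' free signal \code{Wf = W - occ*N} and \code{occ = (Wf/K)/(1 + Wf/K)},
#' a quadratic in the occupied fraction. Used to check that the
#' depletion-free isotherm in \code{\link{gene_occupancy}} is accurate when
#' dimers are in large excess over sites.
#'
#' @param W potency-weighted dimer signal, nM
#' @param K half-saturation constant, nM
#' @param sites total site concentration, nM
#' @return occupied fraction in [0, 1]
#' @export
occupancy_finite_sites <- function(W, K, sites) {
  # occ^2 * N - occ * (W + N + K) + W = 0, smaller root lies in [0, 1]
  if (sites <= 0) return((W / K) / (1 + W / K))
  b <- W + sites + K
  (b - sqrt(b * b - 4 * sites * W)) / (2 * sites)
}
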