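# State vector layout (frozen): amounts in nmol, enzyme/receptor species in nM,
# masses in mg, LH normalized. Trajectory CSV columns follow this order.

.state_names <- c(
  "A1_f", "A2_f", "A3_f",        # finasteride gut / central / peripheral, nmol
  "AT_l", "AD_l",                # liver T / DHT, nmol
  "AT_bl", "AD_bl",              # blood T / DHT, nmol
  "AT_bd", "AD_bd",              # lumped body T / DHT, nmol
  "LH",                          # normalized LH
  "AT_p", "AD_p",                # prostatic T / DHT (free + nonspecific), nmol
  "E", "ET", "EF", "EFstar",     # 5aR2 species, nM
  "AR", "ART", "ARD",            # receptor species, nM
  "VPC_1", "VPL_1"               # androgen-sensitive cellular / lumen mass, mg
)

.ix <- stats::setNames(as.list(seq_along(.state_names)), .state_names)

#' State vector layout
#'
#' @return character vector of the canonical state names, in the frozen order
#'   used by the integrator and by trajectory output.
#' @export
state_names <- function() .state_names

#' Total prostate mass
#'
#' Sum of the basal and androgen-sensitive cellular and ductal-lumen masses,
#' \code{VPC_1 + VPC_2 + VPL_1 + VPL_2}.
#'
#' @param state named state vector (or matrix with state columns)
#' @param p parameter set (for the basal masses)
#' @return mass in mg (vector if \code{state} is a matrix)
#' @export
total_prostate_mass <- function(state, p = prostasim_params()) {
  if (is.matrix(state) || is.data.frame(state))
    return(state[, "VPC_1"] + state[, "VPL_1"] + p$VPC_2 + p$VPL_2)
  unname(state[["VPC_1"]] + state[["VPL_1"]] + p$VPC_2 + p$VPL_2)
}

#' Derived observables from a state
#'
#' Algebraic quantities recomputable from the state vector: free finasteride,
#' free tissue androgen concentrations, dimer concentrations, the four gene
#' occupancies, total prostate mass and prostatic blood flow.
#'
#' @param state named state vector, or matrix/data.frame with state columns
#' @param p parameter set
#' @return named numeric vector (or data.frame for trajectory input) with
#'   elements \code{F_free, CT_l, CD_l, CT_bl, CD_bl, CT_pf, CD_pf, TT, TD,
#'   DD, DNAo_cp, DNAo_cd, DNAo_sec, DNAo_5aR2, V_p, Q_p}
#' @export
derived_observables <- function(state, p = prostasim_params()) {
  g <- if (is.matrix(state) || is.data.frame(state))
    function(nm) state[, nm] else function(nm) state[[nm]]
  V_p <- g("VPC_1") + g("VPL_1") + p$VPC_2 + p$VPL_2
  V_pL <- V_p * 1e-6
  ART <- g("ART"); ARD <- g("ARD")
  TT <- p$kdim * ART^2
  TD <- 2 * p$kdim * ART * ARD
  DD <- p$kdim * ARD^2
  W <- pmax(DD + p$w_TD_eff * TD + TT / p$k_DNAoffTT, 0)
  occ <- function(K) { S <- W / K; S / (1 + S) }
  out <- list(
    F_free = p$fu * g("A2_f") / p$Vc,
    CT_l = g("AT_l") / (p$V_l * p$PT_l),
    CD_l = g("AD_l") / (p$V_l * p$PD_l),
    CT_bl = g("AT_bl") / p$V_bl,
    CD_bl = g("AD_bl") / p$V_bl,
    CT_pf = g("AT_p") / (V_pL * p$PT_p),
    CD_pf = g("AD_p") / (V_pL * p$PD_p),
    TT = TT, TD = TD, DD = DD,
    DNAo_cp = occ(p$K_occ_cp),
    DNAo_cd = occ(p$K_occ_cd),
    DNAo_sec = occ(p$K_occ_sec),
    DNAo_5aR2 = occ(p$K_occ_5aR2),
    V_p = V_p,
    Q_p = p$Qp0 * V_p / p$V_p0
  )
  if (is.matrix(state) || is.data.frame(state)) as.data.frame(out)
  else unlist(out)
}

# build the intact steady-state vector implied by the forcing rules
.initial_state <- function(p) {
  V_pL0 <- p$V_p0 * 1e-6
  x <- numeric(length(.state_names))
  names(x) <- .state_names
  x["AT_l"] <- p$CT_l0 * p$V_l * p$PT_l
  x["AD_l"] <- p$CD_l0 * p$V_l * p$PD_l
  x["AT_bl"] <- p$CT_bl0 * p$V_bl
  x["AD_bl"] <- p$CD_bl0 * p$V_bl
  x["AT_bd"] <- p$CT_bl0 * p$V_bd * p$PT_bd
  x["AD_bd"] <- p$CD_bl0 * p$V_bd * p$PD_bd
  x["LH"] <- p$LH0
  x["AT_p"] <- p$CT_pf0 * V_pL0 * p$PT_p
  x["AD_p"] <- p$CD_pf0 * V_pL0 * p$PD_p
  x["E"] <- p$E_free0
  x["ET"] <- p$ET0
  x["AR"] <- p$AR_free0
  x["ART"] <- p$ART0
  x["ARD"] <- p$ARD0
  x["VPC_1"] <- p$VPC_1b
  x["VPL_1"] <- p$VPL_1b
  x
}
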