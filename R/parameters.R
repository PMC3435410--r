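# Parameter set: primary (user-settable) constants plus derived/forced constants
# recomputed by derive_constants(). Units: hours, nmol, nM, mg, L throughout;
# prostate tissue converts as 1 mg = 1 uL.

.primary_defaults <- list(
  ## liver (5aR1 competitive inhibition)
  Q_l = 1.06,      # hepatic plasma flow, L/hr
  V_maxl = 3.65,   # max velocity of hepatic T -> DHT, nmol/hr
  PT_l = 2.75,     # T liver:plasma partition coefficient
  PD_l = 2.0,      # DHT liver:plasma partition coefficient
  K_m5a = 2.3,     # hepatic 5aR1 Km for T, nM
  k_lT = 87.9,     # nonspecific hepatic T elimination, hr^-1 (applied as k*V_l*C)
  k_lD = 77.2,     # nonspecific hepatic DHT elimination, hr^-1 (applied as k*V_l*C)
  Ki_5aR1 = 5.4,   # finasteride Ki on 5aR1, nM
  V_l = 0.0106,    # liver volume, L

  ## prostatic 5aR2 mass-action kinetics (two-step time-dependent inhibition)
  k1 = 500,        # T:5aR2 association, hr^-1 nM^-1
  kcat = 270,      # catalysis T -> DHT, hr^-1
  Km = 0.6,        # prostatic Km for T, nM (fixes k2 = Km*k1 - kcat)
  k3 = 1000,       # finasteride:5aR2 association, hr^-1 nM^-1
  k5 = 3.96,       # reversible -> permanently inhibited complex, hr^-1
  k6 = 0,          # back-isomerization, hr^-1 (zero: pure sink)
  Ki_5aR2 = 0.5,   # finasteride Ki on 5aR2, nM (fixes k4 = Ki*k3)
  k_dg = 0.016,    # 5aR2 degradation (E, EF, EF*), hr^-1
  E_tot0 = 20,     # total prostatic 5aR2 at intact steady state, nM
  E_free0 = 19,    # free 5aR2 at intact steady state, nM
  DNAo_5aR20 = 0.95, # intact 5aR2-gene occupancy anchor

  ## prostate mass dynamics
  k_cp1 = 0.5,     # proliferation rate constant, mg/hr
  VPC_1b = 191,    # intact androgen-sensitive cellular mass, mg
  VPC_2 = 18,      # basal cellular mass, mg
  VPL_2 = 18.2,    # basal ductal lumen mass, mg
  V_p0 = 457,      # intact total prostate mass, mg (fixes VPL_1b)
  k_sec = 3.5,     # fluid production rate constant, mg/hr
  DNAo_cp0 = 0.8,  # intact occupancy anchors for proliferation /
  DNAo_cd0 = 0.8,  #   anti-apoptosis /
  DNAo_sec0 = 0.8, #   fluid production genes (calibrated; 5aR2 anchor printed)

  ## AR binding, dimerization, gene occupancy
  k_DNAoffTT = 1.6,# relative potency divisor for TT homodimers on DNA
  w_TD = 0.25,     # TD heterodimer DNA potency weight (calibrated;
                   # NA -> geometric-mean fallback 1/sqrt(k_DNAoffTT))
  kdim = 0.001,    # dimer association constant, nM^-1 (quasi-equilibrium)
  konT = 0.15,     # AR:T association, hr^-1 nM^-1  (KdT = koffT/konT = 200 nM)
  koffT = 30,      # AR:T dissociation, hr^-1
  konD = 0.75,     # AR:DHT association, hr^-1 nM^-1 (KdD = 40 nM)
  koffD = 30,      # AR:DHT dissociation, hr^-1
  kAR_deg = 0.08,  # AR (free and liganded) degradation, hr^-1
  AR_free0 = 15,   # free AR at intact steady state, nM

  ## endocrine axis / PBPK
  CT_bl0 = 6,      # intact blood T anchor, nM
  CD_bl0 = 0.3,    # intact blood DHT anchor, nM
  V_bl = 0.022,    # blood volume, L
  V_bd = 0.25,     # lumped body volume, L
  PT_bd = 1,       # body partition coefficients
  PD_bd = 1,
  Q_bd = 1.3,      # blood flow to lumped body, L/hr
  PT_p = 2,        # nonspecific prostate partition: T fast/lean,
  PD_p = 60,       #   DHT heavily tissue-bound (smooths free-DHT kinetics)
  kLH_deg = 2.3,   # LH turnover, hr^-1
  LH0 = 1,         # normalized intact LH level
  K_inh = 10.5,    # feedback half-inhibition constant on the sensed signal, nM
  n_LH = 6,        # feedback Hill coefficient
  w_DHT_fb = 15,   # DHT potency weight in the sensed feedback signal
  k_elT_bl = 0,    # extra central T clearance, hr^-1 (default none)

  ## finasteride PK (2-compartment oral)
  ka = 2,          # absorption, hr^-1
  k10 = 1.1,       # central elimination, hr^-1
  k12 = 0.02,      # central -> peripheral, hr^-1 (small, slow deep pool)
  k21 = 0.10,      # peripheral -> central, hr^-1
  Vc = 0.25,       # central volume, L
  fu = 0.10,       # fraction unbound in plasma
  MW_F = 372.55,   # finasteride molecular weight, g/mol
  BW = 0.35        # body weight, kg (mg/kg -> mg conversion only)
)

.derived_names <- c(
  "k2", "k4", "ET0", "CT_pf0", "CD_pf0", "VPL_1b", "k_cd1", "k_lum",
  "Qp0", "CT_l0", "CD_l0", "kT_prod", "kLH_prod", "k_elD_bl", "kAR_syn",
  "ART0", "ARD0", "K_occ_cp", "K_occ_cd", "K_occ_sec", "K_occ_5aR2",
  "w_TD_eff"
)

.must_be_positive <- c(
  "Q_l", "V_maxl", "PT_l", "PD_l", "K_m5a", "k_lT", "k_lD", "Ki_5aR1", "V_l",
  "k1", "kcat", "Km", "k3", "k5", "Ki_5aR2", "k_dg", "E_tot0", "E_free0",
  "k_cp1", "VPC_1b", "VPC_2", "VPL_2", "V_p0", "k_sec",
  "kdim", "konT", "koffT", "konD", "koffD", "kAR_deg", "AR_free0",
  "CT_bl0", "CD_bl0", "V_bl", "V_bd", "PT_bd", "PD_bd", "Q_bd", "PT_p", "PD_p",
  "kLH_deg", "LH0", "K_inh", "n_LH", "w_DHT_fb",
  "ka", "k10", "k12", "k21", "Vc", "fu", "MW_F", "BW"
)

.must_be_nonnegative <- c("k6", "k_elT_bl", "k_DNAoffTT")

.anchor_names <- c("DNAo_5aR20", "DNAo_cp0", "DNAo_cd0", "DNAo_sec0")

#' Construct a validated model parameter set
#'
#' Builds the full parameter list for the prostate-maintenance model: the
#' primary constants (rate constants, volumes, flows, partition coefficients,
#' steady-state anchors) plus every derived and steady-state-forced constant
#' (\code{k2}, \code{k4}, the death/clearance constants, the axis production
#' rates, the per-gene occupancy half-saturation constants, ...). Derived
#' entries are recomputed from the primaries, so perturbing e.g. \code{Km}
#' propagates to \code{k2} on reconstruction.
#'
#' @param ... named overrides of primary parameters (see
#'   \code{prostasim_defaults()} for the names and units). Unknown names and
#'   attempts to set derived constants directly are an error.
#' @param .list optional named list of overrides, merged after \code{...}.
#' @return an object of class \code{prostasim_params}: a named list of
#'   numeric scalars (primary and derived) with the derived-constant names in
#'   \code{attr(, "derived")}.
#' @examples
#' p <- prostasim_params()
#' p$k2   # 30, from Km * k1 - kcat
#' p2 <- prostasim_params(Km = 0.7)
#' p2$k2  # re-derived
#' @export
prostasim_params <- function(..., .list = NULL) {
  ov <- c(list(...), .list)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(.primary_defaults))
    if (length(bad)) {
      if (any(bad %in% .derived_names))
        stop("derived/forced constants cannot be set directly: ",
             paste(intersect(bad, .derived_names), collapse = ", "))
      stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
    }
  }
  p <- .primary_defaults
  for (nm in names(ov)) p[[nm]] <- as.numeric(ov[[nm]])
  .check_primaries(p)
  validate_params(derive_constants(p))
}

# range checks on the primary constants, run before any derivation so that
# violations are reported by parameter name rather than by a derived identity
.check_primaries <- function(p) {
  for (nm in .must_be_positive)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive finite number")
  for (nm in .must_be_nonnegative)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative")
  if (p$fu > 1) stop("parameter 'fu' must lie in (0, 1]")
  for (nm in .anchor_names)
    if (p[[nm]] <= 0 || p[[nm]] >= 1)
      stop("occupancy anchor '", nm, "' must lie strictly in (0, 1)")
  invisible(p)
}

#' Primary parameter defaults
#'
#' @return named list of the primary (user-settable) parameters with their
#'   default values.
#' @export
prostasim_defaults <- function() .primary_defaults

#' Dissociation rate constant for the T:5aR2 complex
#'
#' Applies the relation \code{k2 = Km * k1 - kcat} linking the Michaelis
#' constant of prostatic T metabolism to the mass-action rate constants.
#'
#' @param Km Michaelis constant, nM
#' @param k1 association rate constant, hr^-1 nM^-1
#' @param kcat catalytic rate constant, hr^-1
#' @return k2 in hr^-1 (strictly positive)
#' @export
derive_k2 <- function(Km, k1, kcat) {
  k2 <- Km * k1 - kcat
  if (k2 <= 0)
    stop("Km * k1 must exceed kcat (got k2 = ", signif(k2, 4), " hr^-1)")
  k2
}

#' Dissociation rate constant for the finasteride:5aR2 complex
#'
#' Applies \code{k4 = Ki_5aR2 * k3}.
#'
#' @param Ki_5aR2 inhibition constant, nM
#' @param k3 association rate constant, hr^-1 nM^-1
#' @return k4 in hr^-1
#' @export
derive_k4 <- function(Ki_5aR2, k3) {
  if (Ki_5aR2 <= 0 || k3 <= 0) stop("Ki_5aR2 and k3 must be positive")
  Ki_5aR2 * k3
}

#' Steady-state-forced prostate death and lumen clearance constants
#'
#' The apoptosis constant is forced so that cellular mass is stationary at the
#' intact anchors: \code{k_cd1 = k_cp1 * DNAo_cp0 / ((1 - DNAo_cd0) * VPC_1b)};
#' the lumen clearance likewise: \code{k_lum = k_sec * DNAo_sec0 / VPL_1b}.
#'
#' @param p parameter list containing \code{k_cp1}, \code{k_sec}, the
#'   occupancy anchors and \code{VPC_1b}; \code{VPL_1b} is taken from the list
#'   or recomputed from \code{V_p0}.
#' @return list with \code{k_cd1}, \code{k_sec}, \code{k_lum}
#' @export
force_death_constants <- function(p) {
  if (p$DNAo_cd0 >= 1)
    stop("DNAo_cd0 must be < 1: forced apoptosis constant divides by (1 - DNAo_cd0)")
  VPL_1b <- p$VPL_1b
  if (is.null(VPL_1b)) VPL_1b <- p$V_p0 - p$VPC_1b - p$VPC_2 - p$VPL_2
  if (VPL_1b <= 0) stop("V_p0 must exceed VPC_1b + VPC_2 + VPL_2")
  list(k_cd1 = p$k_cp1 * p$DNAo_cp0 / ((1 - p$DNAo_cd0) * p$VPC_1b),
       k_sec = p$k_sec,
       k_lum = p$k_sec * p$DNAo_sec0 / VPL_1b)
}

# Hepatic free T concentration solving the intact liver T balance
# Q_l (CT_bl0 - C) - Vmax C/(Km + C) - k_lT V_l C = 0  (positive quadratic root)
.liver_T_steady <- function(p) {
  a <- p$Q_l + p$k_lT * p$V_l
  b <- a * p$K_m5a + p$V_maxl - p$Q_l * p$CT_bl0
  cc <- -p$Q_l * p$CT_bl0 * p$K_m5a
  (-b + sqrt(b * b - 4 * a * cc)) / (2 * a)
}

#' Recompute all derived and steady-state-forced constants
#'
#' Idempotent: applies the structural identities (\code{k2}, \code{k4},
#' \code{VPL_1b}, the TD weight) and the forcing rules that pin the intact
#' steady state to its anchors (death constants, prostatic blood flow, axis
#' production and clearance rates, AR synthesis, per-gene occupancy constants).
#'
#' @param p parameter list (primary entries at least)
#' @return the list with every derived entry filled in
#' @export
derive_constants <- function(p) {
  p$k2 <- derive_k2(p$Km, p$k1, p$kcat)
  p$k4 <- derive_k4(p$Ki_5aR2, p$k3)
  p$w_TD_eff <- if (is.na(p$w_TD)) 1 / sqrt(p$k_DNAoffTT) else p$w_TD
  p$ET0 <- p$E_tot0 - p$E_free0
  if (p$ET0 <= 0) stop("E_tot0 must exceed E_free0")
  # free prostatic T pinned by the enzyme branch: ET/E = CT_pf/Km at steady state
  p$CT_pf0 <- p$Km * p$ET0 / p$E_free0
  p$VPL_1b <- p$V_p0 - p$VPC_1b - p$VPC_2 - p$VPL_2
  fd <- force_death_constants(p)
  p$k_cd1 <- fd$k_cd1
  p$k_lum <- fd$k_lum

  # prostate flow forced from the intact T balance; DHT gradient mirrors it
  V_pL0 <- p$V_p0 * 1e-6
  conv0 <- p$kcat * p$ET0 * V_pL0              # nmol/hr T -> DHT in prostate
  if (p$CT_bl0 <= p$CT_pf0)
    stop("CT_bl0 must exceed the forced intact free prostatic T (", signif(p$CT_pf0, 4), " nM)")
  p$Qp0 <- conv0 / (p$CT_bl0 - p$CT_pf0)
  p$CD_pf0 <- p$CD_bl0 + conv0 / p$Qp0

  # hepatic steady state and forced axis constants
  p$CT_l0 <- .liver_T_steady(p)
  mm0 <- p$V_maxl * p$CT_l0 / (p$K_m5a + p$CT_l0)
  p$CD_l0 <- (p$Q_l * p$CD_bl0 + mm0) / (p$Q_l + p$k_lD * p$V_l)
  p$kT_prod <- (p$Q_l * (p$CT_bl0 - p$CT_l0) + p$Qp0 * (p$CT_bl0 - p$CT_pf0) +
                  p$k_elT_bl * p$V_bl * p$CT_bl0) / p$LH0
  sensed0 <- p$CT_bl0 + p$w_DHT_fb * p$CD_bl0
  p$kLH_prod <- p$kLH_deg * p$LH0 * (1 + (sensed0 / p$K_inh)^p$n_LH)
  RD <- p$Q_l * (p$CD_l0 - p$CD_bl0) + p$Qp0 * (p$CD_pf0 - p$CD_bl0)
  if (RD <= 0) stop("intact anchors imply no net DHT delivery to blood; check liver parameters")
  p$k_elD_bl <- RD / (p$V_bl * p$CD_bl0)

  # AR pools and forced synthesis at the intact anchors
  p$ART0 <- p$konT * p$CT_pf0 * p$AR_free0 / (p$koffT + p$kAR_deg)
  p$ARD0 <- p$konD * p$CD_pf0 * p$AR_free0 / (p$koffD + p$kAR_deg)
  p$kAR_syn <- p$kAR_deg * (p$AR_free0 + p$ART0 + p$ARD0)

  # per-gene occupancy constants pinned so intact occupancy equals its anchor
  dm <- dimer_concentrations(p$ART0, p$ARD0, p)
  W0 <- dm[["DD"]] + p$w_TD_eff * dm[["TD"]] + dm[["TT"]] / p$k_DNAoffTT
  for (g in c("cp", "cd", "sec", "5aR2")) {
    anc <- p[[paste0("DNAo_", sub("5aR2", "5aR2", g), "0")]]
    p[[paste0("K_occ_", g)]] <- W0 * (1 - anc) / anc
  }
  p
}

#' Validate a parameter set
#'
#' Checks positivity/range constraints and the structural identities; raises
#' an error naming the offending parameter.
#'
#' @param p parameter list with derived constants present
#' @return the list, classed \code{prostasim_params}, invisibly usable onward
#' @export
validate_params <- function(p) {
  miss <- setdiff(names(.primary_defaults), names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  for (nm in .must_be_positive)
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be a positive finite number")
  for (nm in .must_be_nonnegative)
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop("parameter '", nm, "' must be non-negative")
  if (p$fu > 1) stop("parameter 'fu' must lie in (0, 1]")
  for (nm in .anchor_names)
    if (p[[nm]] <= 0 || p[[nm]] >= 1)
      stop("occupancy anchor '", nm, "' must lie strictly in (0, 1)")
  if (p$k2 <= 0) stop("derived k2 = Km*k1 - kcat must be positive")
  structure(p, class = "prostasim_params", derived = .derived_names)
}

#' @export
print.prostasim_params <- function(x, ...) {
  cat("<prostasim_params>\n")
  cat(sprintf("  intact anchors: blood T %.3g nM, blood DHT %.3g nM, prostate %.4g mg\n",
              x$CT_bl0, x$CD_bl0, x$V_p0))
  cat(sprintf("  5aR2 pool: total %.3g nM (free %.3g, bound %.3g); k2 = %.4g, k4 = %.4g hr^-1\n",
              x$E_tot0, x$E_free0, x$ET0, x$k2, x$k4))
  cat(sprintf("  forced: Qp0 = %.4g L/hr, k_cd1 = %.4g hr^-1, k_lum = %.4g hr^-1, kT_prod = %.4g nmol/hr\n",
              x$Qp0, x$k_cd1, x$k_lum, x$kT_prod))
  cat(sprintf("  %d primary + %d derived constants\n",
              length(.primary_defaults), length(.derived_names)))
  invisible(x)
}

#' Prostatic 5aR2 pool estimate from tissue protein content
#'
#' Back-of-envelope concentration of 5aR2 in ventral prostate tissue assuming
#' the enzyme is a stated mass fraction of total tissue protein and 1 g tissue
#' occupies 1 mL.
#'
#' @param fraction enzyme mass fraction of total protein (default 1e-5, i.e. 0.001\%)
#' @param protein_mg_per_g total protein, mg per g tissue (default 53)
#' @param mw enzyme molecular weight, g/mol (default 28772)
#' @return concentration in nM
#' @examples
#' enzyme_pool_estimate()  # ~18.4 nM
#' @export
enzyme_pool_estimate <- function(fraction = 1e-5, protein_mg_per_g = 53,
                                 mw = 28772) {
  # mg/g -> g/L tissue water (1 g = 1 mL), / (g/mol) -> mol/L, * 1e9 -> nM
  protein_mg_per_g * fraction * 1e9 / mw
}

#' Mean lifetime of prostatic 5aR2
#'
#' \code{1/k_dg}, the mean residence time of the enzyme; sets the timescale of
#' DHT recovery after drug washout.
#'
#' @param p parameter set (uses \code{k_dg})
#' @param units "days" (default) or "hours"
#' @return mean lifetime in the requested units
#' @export
enzyme_mean_lifetime <- function(p = prostasim_params(), units = c("days", "hours")) {
  units <- match.arg(units)
  h <- 1 / p$k_dg
  if (units == "days") h / 24 else h
}
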