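/* Compiled system derivative for the prostate-maintenance model.
 * Mirrors model_derivative() in R/derivative.R exactly; a testthat check
 * asserts agreement between the two on random states. Parameter order must
 * match .c_param_order in R/simulate.R. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define N_PARMS 62
static double parms[N_PARMS];

enum {
  i_fu, i_Vc, i_VPC_2, i_VPL_2, i_V_p0, i_Qp0, i_V_bl, i_V_l,
  i_PT_l, i_PD_l, i_PT_p, i_PD_p, i_PT_bd, i_PD_bd, i_V_bd,
  i_Q_l, i_Q_bd, i_V_maxl, i_K_m5a, i_Ki_5aR1, i_k_lT, i_k_lD,
  i_kdim, i_w_TD_eff, i_k_DNAoffTT,
  i_K_occ_cp, i_K_occ_cd, i_K_occ_sec, i_K_occ_5aR2,
  i_k_cp1, i_k_cd1, i_k_sec, i_k_lum,
  i_k_dg, i_E_free0, i_DNAo_5aR20,
  i_k1, i_k2, i_kcat, i_k3, i_k4, i_k5, i_k6,
  i_konT, i_koffT, i_konD, i_koffD, i_kAR_syn, i_kAR_deg,
  i_kT_prod, i_kLH_prod, i_kLH_deg, i_K_inh, i_n_LH, i_w_DHT_fb,
  i_k_elT_bl, i_k_elD_bl,
  i_ka, i_k10, i_k12, i_k21,
  i_castration_time
};

void prostasim_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARMS;
  odeparms(&n, parms);
}

void prostasim_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
  const double A1 = y[0], A2 = y[1], A3 = y[2];
  const double AT_l = y[3], AD_l = y[4];
  const double AT_bl = y[5], AD_bl = y[6];
  const double AT_bd = y[7], AD_bd = y[8];
  const double LH = y[9];
  const double AT_p = y[10], AD_p = y[11];
  const double E = y[12], ET = y[13], EF = y[14], EFstar = y[15];
  const double AR = y[16], ART = y[17], ARD = y[18];
  const double VPC_1 = y[19], VPL_1 = y[20];

  const double F_free = parms[i_fu] * A2 / parms[i_Vc];
  const double V_p = VPC_1 + VPL_1 + parms[i_VPC_2] + parms[i_VPL_2];
  const double V_pL = V_p * 1e-6;
  const double Q_p = parms[i_Qp0] * V_p / parms[i_V_p0];
  const double CT_bl = AT_bl / parms[i_V_bl];
  const double CD_bl = AD_bl / parms[i_V_bl];
  const double CT_pf = AT_p / (V_pL * parms[i_PT_p]);
  const double CD_pf = AD_p / (V_pL * parms[i_PD_p]);

  /* algebraic dimers and occupancies */
  const double TT = parms[i_kdim] * ART * ART;
  const double TD = 2.0 * parms[i_kdim] * ART * ARD;
  const double DD = parms[i_kdim] * ARD * ARD;
  double W = DD + parms[i_w_TD_eff] * TD + TT / parms[i_k_DNAoffTT];
  if (W < 0.0) W = 0.0;
  const double occ_cp = (W / parms[i_K_occ_cp]) / (1.0 + W / parms[i_K_occ_cp]);
  const double occ_cd = (W / parms[i_K_occ_cd]) / (1.0 + W / parms[i_K_occ_cd]);
  const double occ_sec = (W / parms[i_K_occ_sec]) / (1.0 + W / parms[i_K_occ_sec]);
  const double occ_a5 = (W / parms[i_K_occ_5aR2]) / (1.0 + W / parms[i_K_occ_5aR2]);

  /* prostate mass (sets the dilution rate of concentration species) */
  const double dVPC_1 = parms[i_k_cp1] * occ_cp
    - parms[i_k_cd1] * (1.0 - occ_cd) * VPC_1;
  const double dVPL_1 = parms[i_k_sec] * occ_sec - parms[i_k_lum] * VPL_1;
  const double dil = (dVPC_1 + dVPL_1) / V_p;

  /* prostatic 5aR2 kinetics */
  const double E_syn = parms[i_k_dg] * parms[i_E_free0]
    * (occ_a5 / parms[i_DNAo_5aR20]);
  const double bindT = parms[i_k1] * CT_pf * E - parms[i_k2] * ET;
  const double bindF = parms[i_k3] * F_free * E - parms[i_k4] * EF;
  const double cat_rel = (parms[i_k2] + parms[i_kcat]) * ET;
  const double dE = E_syn - parms[i_k_dg] * E - parms[i_k1] * CT_pf * E
    + cat_rel - bindF;
  const double dET = parms[i_k1] * CT_pf * E - cat_rel;
  const double dEF = bindF - parms[i_k5] * EF + parms[i_k6] * EFstar
    - parms[i_k_dg] * EF;
  const double dEFstar = parms[i_k5] * EF - parms[i_k6] * EFstar
    - parms[i_k_dg] * EFstar;

  /* AR binding; ligand in degraded complexes returns to the free pool */
  const double bT = parms[i_konT] * CT_pf * AR - parms[i_koffT] * ART;
  const double bD = parms[i_konD] * CD_pf * AR - parms[i_koffD] * ARD;
  const double dAR = parms[i_kAR_syn] - parms[i_kAR_deg] * AR - bT - bD;
  const double dART = bT - parms[i_kAR_deg] * ART;
  const double dARD = bD - parms[i_kAR_deg] * ARD;
  const double T_net = bT - parms[i_kAR_deg] * ART;
  const double D_net = bD - parms[i_kAR_deg] * ARD;

  /* liver */
  const double CT_l = AT_l / (parms[i_V_l] * parms[i_PT_l]);
  const double CD_l = AD_l / (parms[i_V_l] * parms[i_PD_l]);
  const double mm = parms[i_V_maxl] * CT_l /
    (parms[i_K_m5a] * (1.0 + F_free / parms[i_Ki_5aR1]) + CT_l);
  const double upT_l = parms[i_Q_l] * (CT_bl - CT_l);
  const double upD_l = parms[i_Q_l] * (CD_bl - CD_l);

  /* prostate androgen balances */
  const double upT_p = Q_p * (CT_bl - CT_pf);
  const double upD_p = Q_p * (CD_bl - CD_pf);

  /* lumped body */
  const double upT_bd = parms[i_Q_bd] * (CT_bl - AT_bd / (parms[i_V_bd] * parms[i_PT_bd]));
  const double upD_bd = parms[i_Q_bd] * (CD_bl - AD_bd / (parms[i_V_bd] * parms[i_PD_bd]));

  /* testes (castration removes production from castration_time on) */
  double prod_T = parms[i_kT_prod] * LH;
  if (*t >= parms[i_castration_time]) prod_T = 0.0;

  const double ratio = (CT_bl + parms[i_w_DHT_fb] * CD_bl) / parms[i_K_inh];
  const double dLH = parms[i_kLH_prod] / (1.0 + pow(ratio, parms[i_n_LH]))
    - parms[i_kLH_deg] * LH;

  ydot[0] = -parms[i_ka] * A1;
  ydot[1] = parms[i_ka] * A1 - (parms[i_k10] + parms[i_k12]) * A2
    + parms[i_k21] * A3 - bindF * V_pL;
  ydot[2] = parms[i_k12] * A2 - parms[i_k21] * A3;
  ydot[3] = upT_l - mm - parms[i_k_lT] * parms[i_V_l] * CT_l;
  ydot[4] = upD_l + mm - parms[i_k_lD] * parms[i_V_l] * CD_l;
  ydot[5] = prod_T - upT_l - upT_bd - upT_p
    - parms[i_k_elT_bl] * parms[i_V_bl] * CT_bl;
  ydot[6] = -upD_l - upD_bd - upD_p
    - parms[i_k_elD_bl] * parms[i_V_bl] * CD_bl;
  ydot[7] = upT_bd;
  ydot[8] = upD_bd;
  ydot[9] = dLH;
  ydot[10] = upT_p - (bindT + T_net) * V_pL;
  ydot[11] = upD_p + (parms[i_kcat] * ET - D_net) * V_pL;
  ydot[12] = dE - dil * E;
  ydot[13] = dET - dil * ET;
  ydot[14] = dEF - dil * EF;
  ydot[15] = dEFstar - dil * EFstar;
  ydot[16] = dAR - dil * AR;
  ydot[17] = dART - dil * ART;
  ydot[18] = dARD - dil * ARD;
  ydot[19] = dVPC_1;
  ydot[20] = dVPL_1;
}
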