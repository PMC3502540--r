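/* Compiled right-hand sides of the two HPA-axis feedback models, in the
 * deSolve compiled-model convention (initfunc receives the parameter
 * vector, derivs fills ydot).  Mirrors the reference R implementations
 * parsimonious_rhs()/extended_rhs(); the two are cross-checked in the
 * test suite.
 *
 * Units: minutes and nM throughout.  Extracellular CRH and cortisol are
 * algebraic forcings dose * exp(-k_dec * t) (a decay rate of ~0 is a clamp).
 */

#include <R.h>
#include <math.h>

/* ---------------- parsimonious model (4 species; in vitro the two
 * extracellular inputs are forcings, leaving ACTH and GR as states) -----
 * parms: 1 k_base, 2 k_crh, 3 k_acth_deg, 4 K_i, 5 k_gr_up, 6 K_gr,
 *        7 k_gr_basal, 8 k_gr_deg, 9 k_crh_dec, 10 k_cort_dec,
 *        11 crh_dose, 12 cort_dose
 * states: 1 acth_ex, 2 gr
 */

static double pparms[12];

void acthfcs_init_parsimonious(void (*odeparms)(int *, double *)) {
    int n = 12;
    odeparms(&n, pparms);
}

void acthfcs_derivs_parsimonious(int *neq, double *t, double *y, double *ydot,
                                 double *yout, int *ip) {
    const double *p = pparms;
    double crh  = p[10] * exp(-p[8] * (*t));
    double cort = p[11] * exp(-p[9] * (*t));
    double A = y[0], R = y[1];
    double occ = cort * R;                   /* cortisol-GR transcription factor */
    double inhib = 1.0 + occ / p[3];
    double occ2 = occ * occ;
    ydot[0] = (p[0] + p[1] * crh) / inhib - p[2] * A;
    ydot[1] = p[4] * occ2 / (p[5] * p[5] + occ2) + p[6] - p[7] * R;
}

/* ---------------- extended three-compartment receptor model ------------
 * parms: 1 k_on_crhr, 2 k_off_crhr, 3 k_on_gpcr, 4 k_off_gpcr,
 *        5 k_cort_in, 6 k_cort_deg, 7 k_gr_on, 8 k_gr_off, 9 k_gr_syn,
 *        10 k_gr_deg, 11 k_dim, 12 k_dn_clear, 13 k_tx0, 14 k_tx_crh,
 *        15 K_tx, 16 K_rep, 17 k_mrna_deg, 18 k_transl, 19 k_sec0,
 *        20 k_sec_crh, 21 K_sec_inh, 22 k_acth_loss, 23 k_crh_dec,
 *        24 k_cort_dec, 25 rc_tot, 26 rg_tot, 27 crh_dose, 28 cort_dose
 * states: 1 rc_free, 2 rc_bound, 3 rg_free, 4 rg_bound, 5 cort_in,
 *         6 gr_free, 7 gr_cort, 8 gr_dimer_nuc, 9 pomc_mrna,
 *         10 acth_pool, 11 acth_ex
 */

static double eparms[28];

void acthfcs_init_extended(void (*odeparms)(int *, double *)) {
    int n = 28;
    odeparms(&n, eparms);
}

void acthfcs_derivs_extended(int *neq, double *t, double *y, double *ydot,
                             double *yout, int *ip) {
    const double *p = eparms;
    double crh  = p[26] * exp(-p[22] * (*t));
    double cort = p[27] * exp(-p[23] * (*t));

    double rc_free = y[0], rc_bound = y[1];
    double rg_free = y[2], rg_bound = y[3];
    double cort_in = y[4], gr_free = y[5], gr_cort = y[6];
    double dnuc = y[7], mrna = y[8], pool = y[9], acth_ex = y[10];

    double bind_c  = p[0] * crh * rc_free  - p[1] * rc_bound;
    double bind_g  = p[2] * cort * rg_free - p[3] * rg_bound;
    double bind_gr = p[6] * cort_in * gr_free - p[7] * gr_cort;

    double rep = dnuc / p[15];
    double tx = (p[12] + p[13] * rc_bound / (p[14] + rc_bound))
                / (1.0 + rep * rep);
    double sec_rate = (p[18] + p[19] * rc_bound)
                      / (1.0 + rg_bound / p[20]);
    double secretion = sec_rate * pool;

    ydot[0]  = -bind_c;
    ydot[1]  =  bind_c;
    ydot[2]  = -bind_g;
    ydot[3]  =  bind_g;
    ydot[4]  = p[4] * cort - p[5] * cort_in - bind_gr;
    ydot[5]  = p[8] - p[9] * gr_free - bind_gr;
    ydot[6]  = bind_gr - 2.0 * p[10] * gr_cort * gr_cort;
    ydot[7]  = p[10] * gr_cort * gr_cort - p[11] * dnuc;
    ydot[8]  = tx - p[16] * mrna;
    ydot[9]  = p[17] * mrna - secretion;
    ydot[10] = secretion - p[21] * acth_ex;
}
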