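#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_brownian_trace(SEXP box, SEXP d_um2_s, SEXP brightness, SEXP dt_,
                      SEXP n_bins_, SEXP r_um_, SEXP z_um_, SEXP seed_,
                      SEXP init_pos);

void acthfcs_init_parsimonious(void (*odeparms)(int *, double *));
void acthfcs_derivs_parsimonious(int *neq, double *t, double *y, double *ydot,
                                 double *yout, int *ip);
void acthfcs_init_extended(void (*odeparms)(int *, double *));
void acthfcs_derivs_extended(int *neq, double *t, double *y, double *ydot,
                             double *yout, int *ip);

static const R_CallMethodDef call_entries[] = {
    {"C_brownian_trace", (DL_FUNC) &C_brownian_trace, 9},
    {NULL, NULL, 0}
};

void R_init_acthfcs(DllInfo *dll) {
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* deSolve looks the derivs/init functions up by name */
    R_useDynamicSymbols(dll, TRUE);
}
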