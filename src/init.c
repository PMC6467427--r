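#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ldl_inertia(SEXP Amat, SEXP tol_);
SEXP C_propagate(SEXP times_, SEXP kind_, SEXP dfac_, SEXP x0_, SEXP mu_,
                 SEXP alpha_, SEXP Ksat_, SEXP sens_, SEXP tol_,
                 SEXP maxit_, SEXP cap_);

static const R_CallMethodDef CallEntries[] = {
    {"C_ldl_inertia", (DL_FUNC) &C_ldl_inertia, 2},
    {"C_propagate", (DL_FUNC) &C_propagate, 11},
    {NULL, NULL, 0}
};

void R_init_glvdirect(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
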