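#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void set_pbpk_parms(double *v, int *n);
void derivs_pbpk(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"set_pbpk_parms", (DL_FUNC) &set_pbpk_parms, 2},
    {"derivs_pbpk",    (DL_FUNC) &derivs_pbpk,    6},
    {NULL, NULL, 0}
};

void R_init_cabopbpk(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
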