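#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void pp_initmod(void (*odeparms)(int *, double *));
void pp_initforc(void (*odeforcs)(int *, double *));
void pp_derivs(int *neq, double *t, double *p, double *dp,
               double *yout, int *ip);

static const R_CMethodDef cMethods[] = {
    {"pp_initmod",  (DL_FUNC) &pp_initmod,  1},
    {"pp_initforc", (DL_FUNC) &pp_initforc, 1},
    {"pp_derivs",   (DL_FUNC) &pp_derivs,   6},
    {NULL, NULL, 0}
};

void R_init_penpress(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
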