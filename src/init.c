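#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ceriakin_nondim_init(void (*odeparms)(int *, double *));
void ceriakin_nondim_deriv(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip);
void ceriakin_dim_init(void (*odeparms)(int *, double *));
void ceriakin_dim_deriv(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip);

/* deSolve looks these up by name via getNativeSymbolInfo(); register them
 * but keep dynamic lookup allowed. */
static const R_CMethodDef c_entries[] = {
    {"ceriakin_nondim_init",  (DL_FUNC) &ceriakin_nondim_init,  0},
    {"ceriakin_nondim_deriv", (DL_FUNC) &ceriakin_nondim_deriv, 0},
    {"ceriakin_dim_init",     (DL_FUNC) &ceriakin_dim_init,     0},
    {"ceriakin_dim_deriv",    (DL_FUNC) &ceriakin_dim_deriv,    0},
    {NULL, NULL, 0}
};

void R_init_ceriakin(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
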