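#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void ffamm_init_mod1(void (*odeparms)(int *, double *));
void ffamm_forc_mod1(void (*odeforcs)(int *, double *));
void ffamm_derivs_mod1(int *, double *, double *, double *, double *, int *);
void ffamm_init_mod2(void (*odeparms)(int *, double *));
void ffamm_forc_mod2(void (*odeforcs)(int *, double *));
void ffamm_derivs_mod2(int *, double *, double *, double *, double *, int *);
void ffamm_init_mod3(void (*odeparms)(int *, double *));
void ffamm_forc_mod3(void (*odeforcs)(int *, double *));
void ffamm_derivs_mod3(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"ffamm_init_mod1",   (DL_FUNC) &ffamm_init_mod1,   1},
    {"ffamm_forc_mod1",   (DL_FUNC) &ffamm_forc_mod1,   1},
    {"ffamm_derivs_mod1", (DL_FUNC) &ffamm_derivs_mod1, 6},
    {"ffamm_init_mod2",   (DL_FUNC) &ffamm_init_mod2,   1},
    {"ffamm_forc_mod2",   (DL_FUNC) &ffamm_forc_mod2,   1},
    {"ffamm_derivs_mod2", (DL_FUNC) &ffamm_derivs_mod2, 6},
    {"ffamm_init_mod3",   (DL_FUNC) &ffamm_init_mod3,   1},
    {"ffamm_forc_mod3",   (DL_FUNC) &ffamm_forc_mod3,   1},
    {"ffamm_derivs_mod3", (DL_FUNC) &ffamm_derivs_mod3, 6},
    {NULL, NULL, 0}
};

void R_init_ffamm(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
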