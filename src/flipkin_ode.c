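/* Mass-action right-hand side for the three-step base-flipping scheme
 *
 *   N + P <-> NPns <-> NPfl <-> NPst
 *
 * States (micromolar): y = {N, P, NPns, NPfl, NPst}
 * Parameters: p = {k1 (uM^-1 s^-1), k_m1, k2, k_m2, k3, k_m3, k_trap (s^-1)}
 * k_trap is a pseudo-first-order sink on free protein used for
 * competition-chase dissociation; zero for association experiments.
 */
#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[7];

void flipkin_initmod(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void flipkin_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double N = y[0], P = y[1], ns = y[2], fl = y[3], st = y[4];
    double v1 = parms[0] * N * P - parms[1] * ns;
    double v2 = parms[2] * ns - parms[3] * fl;
    double v3 = parms[4] * fl - parms[5] * st;

    ydot[0] = -v1;
    ydot[1] = -v1 - parms[6] * P;
    ydot[2] = v1 - v2;
    ydot[3] = v2 - v3;
    ydot[4] = v3;
}

/* Analytic Jacobian (column-major, 5 x 5); keeps the stiff solver cheap. */
void flipkin_jac(int *neq, double *t, double *y, int *ml, int *mu,
                 double *pd, int *nrowpd, double *yout, int *ip)
{
    int nr = *nrowpd;
    double k1 = parms[0], km1 = parms[1], k2 = parms[2], km2 = parms[3],
           k3 = parms[4], km3 = parms[5], ktr = parms[6];
    double N = y[0], P = y[1];
    int i, j;

    for (j = 0; j < 5; j++)
        for (i = 0; i < 5; i++)
            pd[i + nr * j] = 0.0;

    /* column 0: d/dN */
    pd[0 + nr * 0] = -k1 * P;
    pd[1 + nr * 0] = -k1 * P;
    pd[2 + nr * 0] = k1 * P;
    /* column 1: d/dP */
    pd[0 + nr * 1] = -k1 * N;
    pd[1 + nr * 1] = -k1 * N - ktr;
    pd[2 + nr * 1] = k1 * N;
    /* column 2: d/dNPns */
    pd[0 + nr * 2] = km1;
    pd[1 + nr * 2] = km1;
    pd[2 + nr * 2] = -km1 - k2;
    pd[3 + nr * 2] = k2;
    /* column 3: d/dNPfl */
    pd[2 + nr * 3] = km2;
    pd[3 + nr * 3] = -km2 - k3;
    pd[4 + nr * 3] = k3;
    /* column 4: d/dNPst */
    pd[3 + nr * 4] = km3;
    pd[4 + nr * 4] = -km3;
}

static const R_CMethodDef cMethods[] = {
    {"flipkin_initmod", (DL_FUNC) &flipkin_initmod, 1},
    {"flipkin_derivs",  (DL_FUNC) &flipkin_derivs,  7},
    {"flipkin_jac",     (DL_FUNC) &flipkin_jac,     10},
    {NULL, NULL, 0}
};

void R_init_flipkin(DllInfo *info)
{
    R_registerRoutines(info, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(info, TRUE);
}
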