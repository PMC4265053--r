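/* Mass-action right-hand side for the de-dimensionalized crtEBI pathway
 * model, in the deSolve compiled-model interface. The network structure
 * (reactant/product indices per reversible reaction), rate constants,
 * boundary flags and per-species reference scales are all passed through the
 * parameter vector so the same routine serves any reaction network of this
 * size class.
 *
 * Parameter vector layout (doubles, padded to PARMS_LEN):
 *   [0] n_species  [1] n_reactions
 *   [2 .. 2+4*NR)          r1, r2, p1, p2 per reaction (1-based, 0 = none)
 *   [.. +NR)               kf per reaction
 *   [.. +NR)               kr per reaction
 *   [.. +NS)               boundary flag per species (1 = held fixed)
 *   [.. +NS)               reference scale per species (dimensionless)
 *
 * States are in scaled units z; dimensional concentrations are scale_i * z_i.
 */

#include <R.h>

#define PARMS_LEN 512
#define MAX_SPECIES 64

static double parms[PARMS_LEN];

void pathway_init(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

void pathway_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int ns = (int) parms[0];
    int nr = (int) parms[1];
    const double *ridx = parms + 2;
    const double *kf = parms + 2 + 4 * nr;
    const double *kr = parms + 2 + 5 * nr;
    const double *bnd = parms + 2 + 6 * nr;
    const double *scale = parms + 2 + 6 * nr + ns;
    double ydim[MAX_SPECIES];
    int i, j;

    for (i = 0; i < ns; i++) {
        ydim[i] = scale[i] * y[i];
        ydot[i] = 0.0;
    }
    for (j = 0; j < nr; j++) {
        int r1 = (int) ridx[4 * j] - 1;
        int r2 = (int) ridx[4 * j + 1] - 1;
        int p1 = (int) ridx[4 * j + 2] - 1;
        int p2 = (int) ridx[4 * j + 3] - 1;
        double vf = kf[j];
        double vr = kr[j];
        double v;
        if (r1 >= 0) vf *= ydim[r1];
        if (r2 >= 0) vf *= ydim[r2];
        if (p1 >= 0) vr *= ydim[p1];
        if (p2 >= 0) vr *= ydim[p2];
        v = vf - vr;
        if (r1 >= 0) ydot[r1] -= v;
        if (r2 >= 0) ydot[r2] -= v;
        if (p1 >= 0) ydot[p1] += v;
        if (p2 >= 0) ydot[p2] += v;
    }
    for (i = 0; i < ns; i++) {
        ydot[i] = (bnd[i] > 0.5) ? 0.0 : ydot[i] / scale[i];
    }
}
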