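/* Compiled right-hand side of the glucose-accessibility growth model,
 * used through deSolve's compiled-model interface.
 *
 * States: y[0] = N (live cells), y[1] = D (dead cells),
 *         y[2] = G_total (extracellular glucose, mM).
 * Parameters (in order): k_p, k_d, k_bys, v, theta, G_star, G_min,
 *         G_in, tanh_scale (multiplies t inside tanh; 1 for days).
 */
#include <R.h>
#include <math.h>

static double parms[9];
#define K_P        parms[0]
#define K_D        parms[1]
#define K_BYS      parms[2]
#define V_CONS     parms[3]
#define THETA      parms[4]
#define G_STAR     parms[5]
#define G_MIN      parms[6]
#define G_IN       parms[7]
#define TANH_SCALE parms[8]

void glucodyn_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void glucodyn_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    /* clamp tiny negative excursions of the adaptive solver */
    double n = y[0] > 0 ? y[0] : 0;
    double d = y[1] > 0 ? y[1] : 0;
    double g = y[2] > 0 ? y[2] : 0;

    double g_acs = g / (1 + G_IN * n);
    double s_d = (1 - g_acs / (g_acs + G_MIN)) * tanh(*t * TANH_SCALE);
    double s_p = 1 - s_d;
    double bys = (n + d) > 0 ? K_BYS * n * (d / (d + n)) : 0;

    ydot[0] = K_P * n * (1 - n / THETA) * s_p - K_D * n * s_d - bys;
    ydot[1] = K_D * n * s_d + bys;
    ydot[2] = -V_CONS * n * (g_acs / (g_acs + G_STAR));
}
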