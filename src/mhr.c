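/* Right-hand side of the multi-hit repair chain, compiled for deSolve.
 *
 * State vector y = (L_0, ..., L_kmax, Gamma); length neq = kmax + 2.
 * Parameters (all rates per hour, doses in Gy):
 *   parms[0] alpha     hit induction sensitivity, 1/Gy
 *   parms[1] cr        repair rate constant, 1/h
 *   parms[2] ce        elimination rate constant, 1/h
 *   parms[3] mug       TBDE weighting factor, 1/Gy
 *   parms[4] gam       TBDE repair rate constant, 1/h
 *   parms[5] rate      dose-rate of the current segment, Gy/h (constant:
 *                      the caller splits integration at pulse edges)
 *
 * Boundary rules: L_0 has no hit influx, no repair outflow and no
 * elimination; L_kmax receives no repair influx from above and its hit
 * outflow (alpha * R * L_kmax) leaves the tracked system.
 */
#include <R.h>
#include <math.h>

static double parms[6];
#define p_alpha parms[0]
#define p_cr    parms[1]
#define p_ce    parms[2]
#define p_mug   parms[3]
#define p_gam   parms[4]
#define p_rate  parms[5]

void mhr_init(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

void mhr_deriv(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int n = *neq;
    int kmax = n - 2;
    double G = y[n - 1];
    double pr = p_cr * exp(-p_mug * G); /* effective repair rate */
    double aR = p_alpha * p_rate;
    int i;

    ydot[0] = -aR * y[0] + (kmax >= 1 ? pr * y[1] : 0.0);
    for (i = 1; i < kmax; i++)
        ydot[i] = aR * (y[i - 1] - y[i]) - pr * y[i] + pr * y[i + 1]
                  - p_ce * y[i];
    if (kmax >= 1)
        ydot[kmax] = aR * y[kmax - 1] - aR * y[kmax] - pr * y[kmax]
                     - p_ce * y[kmax];
    ydot[n - 1] = p_rate - p_gam * G;
}
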