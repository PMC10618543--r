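/* Right-hand sides for the six-compartment impulsive BCG model and the
 * legacy four-compartment continuous-instillation model, in the standard
 * deSolve compiled-code form (initfunc + derivs pairs).
 *
 * State ordering, six-compartment model:
 *   y = (B, E, T_i, T_u, H_u, H_i)
 * Parameter vector (set from R, see R/simulate.R):
 *   0..8  p1..p9
 *   9     mu_B     10 mu_E    11 alpha   12 lambda   13 H_m
 *   14    b        15 N       16 tau     17 eps      18 pulse flag (>0.5 on)
 *
 * Legacy model state y = (B, E, T_i, T_u); parameters:
 *   0..4 p1..p5, 5 mu1, 6 mu2, 7 alpha, 8 lambda, 9 b (continuous rate)
 */

#include <R.h>
#include <math.h>

static double parms6[19];
static double parms4[10];

void initmod6(void (*odeparms)(int *, double *))
{
    int n = 19;
    odeparms(&n, parms6);
}

void initmod4(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms4);
}

/* Triangular unit-integral epsilon-approximation of the Dirac comb:
 * pulses of half-width eps centred at m*tau, m = 0..N-1, each with
 * integral b. Peak height b/eps. */
static double dose_rate(double t, double b, double ndoses, double tau,
                        double eps)
{
    int m = (int) floor(t / tau + 0.5);
    double d;
    if (m < 0 || m >= (int) ndoses)
        return 0.0;
    d = fabs(t - m * tau);
    if (d >= eps)
        return 0.0;
    return b * (1.0 - d / eps) / eps;
}

void derivs6(int *neq, double *t, double *y, double *ydot, double *yout,
             int *ip)
{
    double B = y[0], E = y[1], Ti = y[2], Tu = y[3], Hu = y[4], Hi = y[5];
    double p1 = parms6[0], p2 = parms6[1], p3 = parms6[2], p4 = parms6[3];
    double p5 = parms6[4], p6 = parms6[5], p7 = parms6[6], p8 = parms6[7];
    double p9 = parms6[8];
    double muB = parms6[9], muE = parms6[10], alpha = parms6[11];
    double lambda = parms6[12], Hm = parms6[13];
    double dose = 0.0;

    if (parms6[18] > 0.5)
        dose = dose_rate(*t, parms6[14], parms6[15], parms6[16], parms6[17]);

    ydot[0] = dose - p1 * E * B - p2 * B * Tu - p8 * B * Hu - muB * B;
    ydot[1] = -muE * E + alpha * (Ti + Hi) + p4 * E * B - p5 * E * Ti
              - p6 * E * Hi;
    ydot[2] = p2 * B * Tu - p3 * Ti * E;
    ydot[3] = lambda * Tu - p2 * B * Tu - p3 * Tu * E;
    ydot[4] = p7 * Hu * (1.0 - (Hu + Hi + Tu + Ti) / Hm) - p8 * B * Hu;
    ydot[5] = p8 * B * Hu - p9 * E * Hi;
}

/* Batched variant: integrates n = *neq / 6 patients that share one
 * parameter set but differ in initial state, as one system. Used by the
 * fitting loss, where a whole socio-demographic group is simulated per
 * loss evaluation. */
void derivs6b(int *neq, double *t, double *y, double *ydot, double *yout,
              int *ip)
{
    int np = *neq / 6, j;
    double p1 = parms6[0], p2 = parms6[1], p3 = parms6[2], p4 = parms6[3];
    double p5 = parms6[4], p6 = parms6[5], p7 = parms6[6], p8 = parms6[7];
    double p9 = parms6[8];
    double muB = parms6[9], muE = parms6[10], alpha = parms6[11];
    double lambda = parms6[12], Hm = parms6[13];
    double dose = 0.0;

    if (parms6[18] > 0.5)
        dose = dose_rate(*t, parms6[14], parms6[15], parms6[16], parms6[17]);

    for (j = 0; j < np; j++) {
        double *yj = y + 6 * j, *dj = ydot + 6 * j;
        double B = yj[0], E = yj[1], Ti = yj[2], Tu = yj[3], Hu = yj[4],
               Hi = yj[5];
        dj[0] = dose - p1 * E * B - p2 * B * Tu - p8 * B * Hu - muB * B;
        dj[1] = -muE * E + alpha * (Ti + Hi) + p4 * E * B - p5 * E * Ti
                - p6 * E * Hi;
        dj[2] = p2 * B * Tu - p3 * Ti * E;
        dj[3] = lambda * Tu - p2 * B * Tu - p3 * Tu * E;
        dj[4] = p7 * Hu * (1.0 - (Hu + Hi + Tu + Ti) / Hm) - p8 * B * Hu;
        dj[5] = p8 * B * Hu - p9 * E * Hi;
    }
}

void derivs4b(int *neq, double *t, double *y, double *ydot, double *yout,
              int *ip)
{
    int np = *neq / 4, j;
    double p1 = parms4[0], p2 = parms4[1], p3 = parms4[2], p4 = parms4[3];
    double p5 = parms4[4];
    double mu1 = parms4[5], mu2 = parms4[6], alpha = parms4[7];
    double lambda = parms4[8], b = parms4[9];

    for (j = 0; j < np; j++) {
        double *yj = y + 4 * j, *dj = ydot + 4 * j;
        double B = yj[0], E = yj[1], Ti = yj[2], Tu = yj[3];
        dj[0] = -p1 * E * B - p2 * B * Tu - mu1 * B + b;
        dj[1] = -mu2 * E + alpha * Ti + p4 * E * B - p5 * E * Ti;
        dj[2] = p2 * B * Tu - p3 * Ti * E;
        dj[3] = lambda * Tu - p2 * B * Tu;
    }
}

void derivs4(int *neq, double *t, double *y, double *ydot, double *yout,
             int *ip)
{
    double B = y[0], E = y[1], Ti = y[2], Tu = y[3];
    double p1 = parms4[0], p2 = parms4[1], p3 = parms4[2], p4 = parms4[3];
    double p5 = parms4[4];
    double mu1 = parms4[5], mu2 = parms4[6], alpha = parms4[7];
    double lambda = parms4[8], b = parms4[9];

    ydot[0] = -p1 * E * B - p2 * B * Tu - mu1 * B + b;
    ydot[1] = -mu2 * E + alpha * Ti + p4 * E * B - p5 * E * Ti;
    ydot[2] = p2 * B * Tu - p3 * Ti * E;
    ydot[3] = lambda * Tu - p2 * B * Tu;
}
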