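/* Compiled right-hand sides for the HKB oscillators, in the deSolve
 * compiled-model interface.  Parameter layout must match the R wrappers
 * in R/simulate.R:
 *   single : alpha, beta, gamma, omega, rmax
 *   coupled: alpha, beta, gamma, omega1, omega2, a, b, rmax
 * rmax is the blow-up radius used by the root functions. */
#include <R.h>
#include <math.h>

static double ps[5];

void init_hkb_single(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, ps);
}

void derivs_hkb_single(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double alpha = ps[0], beta = ps[1], gamma = ps[2], omega = ps[3];
    ydot[0] = y[1];
    ydot[1] = -y[1] * (alpha * y[0] * y[0] + beta * y[1] * y[1] - gamma)
              - omega * omega * y[0];
}

void root_hkb_single(int *neq, double *t, double *y, int *ng, double *gout,
                     double *out, int *ip)
{
    double m = fabs(y[0]);
    if (fabs(y[1]) > m) m = fabs(y[1]);
    gout[0] = ps[4] - m;
}

static double pc[8];

void init_hkb_coupled(void (*odeparms)(int *, double *))
{
    int n = 8;
    odeparms(&n, pc);
}

void derivs_hkb_coupled(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double alpha = pc[0], beta = pc[1], gamma = pc[2];
    double w1 = pc[3], w2 = pc[4], a = pc[5], b = pc[6];
    double x1 = y[0], x2 = y[1], y1 = y[2], y2 = y[3];
    double d = x1 - x2, cpl = a + b * d * d;
    ydot[0] = y1;
    ydot[1] = y2;
    ydot[2] = cpl * (y1 - y2)
              - (y1 * (alpha * x1 * x1 + beta * y1 * y1 - gamma) + w1 * w1 * x1);
    ydot[3] = cpl * (y2 - y1)
              - (y2 * (alpha * x2 * x2 + beta * y2 * y2 - gamma) + w2 * w2 * x2);
}

void root_hkb_coupled(int *neq, double *t, double *y, int *ng, double *gout,
                      double *out, int *ip)
{
    double m = 0.0;
    for (int i = 0; i < 4; i++)
        if (fabs(y[i]) > m) m = fabs(y[i]);
    gout[0] = pc[7] - m;
}
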