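/* Compiled right-hand sides for the ceria/ROS mass-action network,
 * in the deSolve compiled-model calling convention.
 *
 * Species order everywhere: P (H2O2), O (O2), D (OH-), S (O2-),
 * C (Ce3+), H (H+).  Ce4+ (F) is never integrated: the lattice
 * conservation C + F = Ct makes it algebraic.
 */
#include <R.h>

/* ---- non-dimensional system -------------------------------------- */
/* parameters: a = (k4/k3)*Ct, b = (k4/k1)*Ct, g = (k2/k3)*(k4/k1)^2 */

static double nd_parms[3];

void ceriakin_nondim_init(void (*odeparms)(int *, double *))
{
    int n = 3;
    odeparms(&n, nd_parms);
}

void ceriakin_nondim_deriv(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double P = y[0], O = y[1], D = y[2], S = y[3], C = y[4], H = y[5];
    double a = nd_parms[0], b = nd_parms[1], g = nd_parms[2];
    double m1 = P * O * D * D;       /* peroxide-driven superoxide generation */
    double m2 = (1.0 - C) * S;       /* ceric reduction by superoxide         */
    double m3 = C * S * H * H;       /* cerous oxidation by superoxide        */
    double m4 = P * C * C * H * H;   /* catalase regeneration of ceric        */

    ydot[0] = a * (m3 - m1 - m4);
    ydot[1] = b * (g * m2 - m1);
    ydot[2] = -2.0 * m1;
    ydot[3] = 2.0 * m1 - g * m2 - m3;
    ydot[4] = g * m2 - m3 - 2.0 * m4;
    ydot[5] = -2.0 * b * (m3 + m4);
}

/* ---- dimensional system ------------------------------------------ */
/* parameters: k1, k2, k3, k4, Ct */

static double dm_parms[5];

void ceriakin_dim_init(void (*odeparms)(int *, double *))
{
    int n = 5;
    odeparms(&n, dm_parms);
}

void ceriakin_dim_deriv(int *neq, double *t, double *y, double *ydot,
                        double *yout, int *ip)
{
    double P = y[0], O = y[1], D = y[2], S = y[3], C = y[4], H = y[5];
    double k1 = dm_parms[0], k2 = dm_parms[1], k3 = dm_parms[2],
           k4 = dm_parms[3], Ct = dm_parms[4];
    double r1 = k1 * P * O * D * D;
    double r2 = k2 * (Ct - C) * S;        /* F = Ct - C */
    double r3 = k3 * C * S * H * H;
    double r4 = k4 * P * C * C * H * H;

    ydot[0] = -r1 + r3 - r4;
    ydot[1] = -r1 + r2;
    ydot[2] = -2.0 * r1;
    ydot[3] = 2.0 * r1 - r2 - r3;
    ydot[4] = r2 - r3 - 2.0 * r4;
    ydot[5] = -2.0 * r3 - 2.0 * r4;
}
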