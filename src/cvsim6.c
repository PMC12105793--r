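/* CVSim-6 right-hand side, compiled for use with deSolve (radau / rk4).
 *
 * State vector: six compartment pressures [Pl, Pa, Pv, Pr, Ppa, Ppv] in Barye.
 * Parameters (23, Table-1 order) are passed through deSolve's parms mechanism:
 *   1 Hr (bpm), 2 Pth (mmHg), 3 rsys (-),
 *   4 Cl_dia, 5 Cl_sys, 6 Ca, 7 Cv, 8 Cr_dia, 9 Cr_sys, 10 Cpa, 11 Cpv (ml/Barye),
 *   12 Rl_in, 13 Rl_out, 14 Ra, 15 Rr_in, 16 Rr_out, 17 Rpv (Barye s/ml),
 *   18-23 unstressed volumes (ml, unused by the RHS itself).
 *
 * Ventricular contraction is a time-varying elastance E(t) = 1/C(t):
 * half-cosine rise from diastolic to systolic elastance over systole
 * [0, Ts], half-cosine recovery over [Ts, 1.5 Ts], constant diastolic
 * elastance for the remainder of the cycle (Ts = rsys * 60/Hr).
 */

#include <R.h>
#include <math.h>

#define N_PARMS 23
#define MMHG 1333.22

static double parms[N_PARMS];

void cvsim6_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

/* elastance-based time-varying capacitance and its time derivative */
static void varying_capacitance(double t, double Ttot, double rsys,
                                double Cdia, double Csys,
                                double *C, double *dC)
{
    double Ts = rsys * Ttot;
    double u = fmod(t, Ttot);
    double Edia = 1.0 / Cdia, Esys = 1.0 / Csys;
    double dE = Esys - Edia;
    double E, Edot;

    if (u < 0) u += Ttot;
    if (u <= Ts) {
        E    = Edia + 0.5 * dE * (1.0 - cos(M_PI * u / Ts));
        Edot = 0.5 * dE * (M_PI / Ts) * sin(M_PI * u / Ts);
    } else if (u <= 1.5 * Ts) {
        double v = 2.0 * M_PI * (u - Ts) / Ts;
        E    = Edia + 0.5 * dE * (1.0 + cos(v));
        Edot = -dE * (M_PI / Ts) * sin(v);
    } else {
        E    = Edia;
        Edot = 0.0;
    }
    *C  = 1.0 / E;
    *dC = -Edot / (E * E);
}

void cvsim6_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double Hr = parms[0], Pth = parms[1] * MMHG, rsys = parms[2];
    double Cl_dia = parms[3], Cl_sys = parms[4], Ca = parms[5], Cv = parms[6];
    double Cr_dia = parms[7], Cr_sys = parms[8], Cpa = parms[9], Cpv = parms[10];
    double Rl_in = parms[11], Rl_out = parms[12], Ra = parms[13];
    double Rr_in = parms[14], Rr_out = parms[15], Rpv = parms[16];
    double Ttot = 60.0 / Hr;

    double Pl = y[0], Pa = y[1], Pv = y[2], Pr = y[3], Ppa = y[4], Ppv = y[5];
    double Cl, dCl, Cr, dCr;
    double Ql_in, Ql_out, Qa, Qr_in, Qr_out, Qpv;

    varying_capacitance(*t, Ttot, rsys, Cl_dia, Cl_sys, &Cl, &dCl);
    varying_capacitance(*t, Ttot, rsys, Cr_dia, Cr_sys, &Cr, &dCr);

    Ql_in  = (Ppv > Pl)  ? (Ppv - Pl) / Rl_in   : 0.0;
    Ql_out = (Pl > Pa)   ? (Pl - Pa) / Rl_out   : 0.0;
    Qa     = (Pa - Pv) / Ra;
    Qr_in  = (Pv > Pr)   ? (Pv - Pr) / Rr_in    : 0.0;
    Qr_out = (Pr > Ppa)  ? (Pr - Ppa) / Rr_out  : 0.0;
    Qpv    = (Ppa - Ppv) / Rpv;

    ydot[0] = (Ql_in - Ql_out) / Cl - (Pl - Pth) * dCl / Cl;
    ydot[1] = (Ql_out - Qa) / Ca;
    ydot[2] = (Qa - Qr_in) / Cv;
    ydot[3] = (Qr_in - Qr_out) / Cr - (Pr - Pth) * dCr / Cr;
    ydot[4] = (Qr_out - Qpv) / Cpa;
    ydot[5] = (Qpv - Ql_in) / Cpv;
}
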