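/* Toy ventricular cell model: compiled right-hand side for deSolve.
 *
 * States: y[0]=V (mV), y[1]=f (Ca inactivation gate), y[2]=n (K activation
 * gate), y[3]=Cai (mM), y[4]=Ki (mM), y[5]=qK = running integral of I_K,tot
 * (ms*pA/pF).  The auxiliary state qK makes per-beat potassium budgets exact
 * to solver tolerance without dense output.
 *
 * Must stay numerically identical to the reference R implementation in
 * R/toy_model.R (toy_rhs); the test suite asserts agreement.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 20
static double p[N_PARMS];
/* p: 0 GCa, 1 GK, 2 GK1, 3 GNaK, 4 GKp, 5 GClbk, 6 EClbk, 7 tauf, 8 taun,
 *    9 tauCa, 10 kconv, 11 kK, 12 Ko, 13 Carest, 14 ECa,
 *    15 stim_amp, 16 stim_dur, 17 stim_cl, 18 stim_t0, 19 stim_on */

void toy_init(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, p);
}

void toy_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double V = y[0], f = y[1], n = y[2], Cai = y[3], Ki = y[4];
    double EK, dinf, finf, ninf, k1inf;
    double ICa, IK, IK1, INaK, IKp, IClbk, stim = 0.0, IKtot;

    if (Ki <= 0.0 || p[12] <= 0.0)
        error("toy model: non-positive potassium concentration");

    if (p[19] > 0.5 && *t >= p[18]) {
        double tl = fmod(*t - p[18], p[17]);
        if (tl < p[16]) stim = p[15];
    }

    EK    = 26.71 * log(p[12] / Ki);
    dinf  = 1.0 / (1.0 + exp(-(V + 10.0) / 6.0));
    finf  = 1.0 / (1.0 + exp((V + 25.0) / 6.0));
    ninf  = 1.0 / (1.0 + exp(-(V - 5.0) / 9.0));
    k1inf = 1.0 / (1.0 + exp((V - EK - 12.0) / 12.0));

    ICa   = p[0] * dinf * f * (V - p[14]);
    IK    = p[1] * n * (V - EK);
    IK1   = p[2] * k1inf * (V - EK);
    INaK  = p[3] * (p[12] / (p[12] + 1.5)) / (1.0 + exp(-(V + 80.0) / 25.0));
    IKp   = p[4] * (V - EK) / (1.0 + exp((7.488 - V) / 5.98));
    IClbk = p[5] * (V - p[6]);

    IKtot = IK + IK1 + IKp - 2.0 * INaK + stim;

    ydot[0] = -(ICa + IK + IK1 + INaK + IKp + IClbk + stim);
    ydot[1] = (finf - f) / p[7];
    ydot[2] = (ninf - n) / p[8];
    ydot[3] = -p[10] * ICa - (Cai - p[13]) / p[9];
    ydot[4] = -p[11] * IKtot;
    ydot[5] = IKtot;
}
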