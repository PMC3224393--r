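/* Compiled right-hand side for the reference EGFR-ERK network (27 states).
 *
 * State order (must match .egfr_species_order in R/network.R):
 *  0 EGF  1 EGFR  2 Ra  3 E11  4 E11P  5 Cbl  6 E11P_Cbl  7 GAP  8 E11P_GAP
 *  9 Shc 10 E11P_Shc 11 E11P_ShcP 12 ShcP 13 GS 14 E11P_ShcP_GS 15 ShcP_GS
 * 16 RasGDP 17 RasGTP 18 Raf1 19 Raf1A 20 MEK 21 MEKP 22 MEKPP
 * 23 ERK 24 ERKP 25 ERKPP 26 EGFRdeg
 *
 * Parameter order (must match .egfr_param_order): 51 rate constants in
 * reaction order, then the constant phosphatase pools PP2A, MKP3.
 * EGF is a clamped bath species: dEGF/dt = 0.
 */
#include <R.h>

static double p[53];

void egfr_initmod(void (*odeparms)(int *, double *))
{
    int n = 53;
    odeparms(&n, p);
}

void egfr_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double kf1 = p[0],  kr1 = p[1],  kf2 = p[2],  kr2 = p[3];
    const double k3  = p[4],  V4  = p[5],  Km4 = p[6];
    const double k5  = p[7],  kr5 = p[8],  k6  = p[9];
    const double k7  = p[10], kr7 = p[11], k8  = p[12], kr8 = p[13];
    const double k9  = p[14], kf10 = p[15], kr10 = p[16];
    const double V11 = p[17], Km11 = p[18];
    const double kf12 = p[19], kr12 = p[20], kf13 = p[21], kr13 = p[22];
    const double kf14 = p[23], kr14 = p[24];
    const double kcat15 = p[25], Km15 = p[26], V16 = p[27], Km16 = p[28];
    const double kcat17 = p[29], Km17 = p[30];
    const double kcat18 = p[31], Km18 = p[32], V19 = p[33], Km19 = p[34];
    const double kcat20 = p[35], Km20 = p[36], kcat21 = p[37], Km21 = p[38];
    const double kcat22 = p[39], Km22 = p[40], kcat23 = p[41], Km23 = p[42];
    const double kcat24 = p[43], Km24 = p[44], kcat25 = p[45], Km25 = p[46];
    const double kcat26 = p[47], Km26 = p[48], kcat27 = p[49], Km27 = p[50];
    const double PP2A = p[51], MKP3 = p[52];

    const double EGF = y[0], EGFR = y[1], Ra = y[2], E11 = y[3], E11P = y[4];
    const double Cbl = y[5], E11P_Cbl = y[6], GAP = y[7], E11P_GAP = y[8];
    const double Shc = y[9], E11P_Shc = y[10], E11P_ShcP = y[11];
    const double ShcP = y[12], GS = y[13], E11P_ShcP_GS = y[14];
    const double ShcP_GS = y[15], RasGDP = y[16], RasGTP = y[17];
    const double Raf1 = y[18], Raf1A = y[19];
    const double MEK = y[20], MEKP = y[21], MEKPP = y[22];
    const double ERK = y[23], ERKP = y[24], ERKPP = y[25];

    const double v1  = kf1 * EGF * EGFR - kr1 * Ra;
    const double v2  = kf2 * Ra * Ra - kr2 * E11;
    const double v3  = k3 * E11;
    const double v4  = V4 * E11P / (Km4 + E11P);
    const double v5  = k5 * E11P * Cbl - kr5 * E11P_Cbl;
    const double v6  = k6 * E11P_Cbl;
    const double v7  = k7 * E11P * GAP - kr7 * E11P_GAP;
    const double v8  = k8 * E11P * Shc - kr8 * E11P_Shc;
    const double v9  = k9 * E11P_Shc;
    const double v10 = kf10 * E11P_ShcP - kr10 * E11P * ShcP;
    const double v11 = V11 * ShcP / (Km11 + ShcP);
    const double v12 = kf12 * E11P_ShcP * GS - kr12 * E11P_ShcP_GS;
    const double v13 = kf13 * E11P_ShcP_GS - kr13 * E11P * ShcP_GS;
    const double v14 = kf14 * ShcP_GS - kr14 * ShcP * GS;
    const double v15 = kcat15 * E11P_ShcP_GS * RasGDP / (Km15 + RasGDP);
    const double v16 = V16 * RasGTP / (Km16 + RasGTP);
    const double v17 = kcat17 * E11P_GAP * RasGTP / (Km17 + RasGTP);
    const double v18 = kcat18 * RasGTP * Raf1 / (Km18 + Raf1);
    const double v19 = V19 * Raf1A / (Km19 + Raf1A);
    const double v20 = kcat20 * Raf1A * MEK / (Km20 + MEK);
    const double v21 = kcat21 * PP2A * MEKP / (Km21 + MEKP);
    const double v22 = kcat22 * Raf1A * MEKP / (Km22 + MEKP);
    const double v23 = kcat23 * PP2A * MEKPP / (Km23 + MEKPP);
    const double v24 = kcat24 * MEKPP * ERK / (Km24 + ERK);
    const double v25 = kcat25 * MKP3 * ERKP / (Km25 + ERKP);
    const double v26 = kcat26 * MEKPP * ERKP / (Km26 + ERKP);
    const double v27 = kcat27 * MKP3 * ERKPP / (Km27 + ERKPP);

    ydot[0]  = 0.0;                 /* EGF bath is clamped */
    ydot[1]  = -v1;
    ydot[2]  = v1 - 2.0 * v2;
    ydot[3]  = v2 - v3 + v4;
    ydot[4]  = v3 - v4 - v5 - v7 - v8 + v10 + v13;
    ydot[5]  = -v5 + v6;
    ydot[6]  = v5 - v6;
    ydot[7]  = -v7;
    ydot[8]  = v7;
    ydot[9]  = -v8 + v11;
    ydot[10] = v8 - v9;
    ydot[11] = v9 - v10 - v12;
    ydot[12] = v10 - v11 + v14;
    ydot[13] = -v12 + v14;
    ydot[14] = v12 - v13;
    ydot[15] = v13 - v14;
    ydot[16] = -v15 + v16 + v17;
    ydot[17] = v15 - v16 - v17;
    ydot[18] = -v18 + v19;
    ydot[19] = v18 - v19;
    ydot[20] = -v20 + v21;
    ydot[21] = v20 - v21 - v22 + v23;
    ydot[22] = v22 - v23;
    ydot[23] = -v24 + v25;
    ydot[24] = v24 - v25 - v26 + v27;
    ydot[25] = v26 - v27;
    ydot[26] = v6;
}
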