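/* Coupled overdose system: 2-cmt agonist PK + naloxone PK (optional
 * first-order nasal absorption) + effect sites + competitive mu-receptor
 * binding + lumped cardiorespiratory model.  Must stay in lockstep with
 * the R reference implementation in R/physio.R (physio_derivatives) and
 * R/pk.R; tests compare the two on random states.
 *
 * State vector (17):
 *  0 Af1  agonist central amount (mg)      1 Af2  agonist peripheral (mg)
 *  2 Cef  agonist effect site (nM)         3 And  naloxone depot (mg)
 *  4 An1  naloxone central (mg)            5 An2  naloxone peripheral (mg)
 *  6 Cen  naloxone effect site (nM)        7 Ra   agonist occupancy
 *  8 Rn   naloxone occupancy               9 pA_O2   10 pA_CO2
 * 11 pt_O2  12 pt_CO2  13 pbr_O2  14 pbr_CO2  15 VE  16 CO
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 57
static double p[NPAR];

/* parameter indices (order fixed; see .overdose_parms in R/patient.R) */
#define V1a   p[0]
#define V2a   p[1]
#define CLa   p[2]
#define Qa    p[3]
#define V1n   p[4]
#define V2n   p[5]
#define CLn   p[6]
#define Qn    p[7]
#define KAN   p[8]
#define KE0A  p[9]
#define KE0N  p[10]
#define CONVA p[11]
#define CONVN p[12]
#define KONA  p[13]
#define KOFFA p[14]
#define KONN  p[15]
#define KOFFN p[16]
#define PDFORM p[17]
#define PDFLOOR p[18]
#define PDR50 p[19]
#define PDGAM p[20]
#define VE0   p[21]
#define CO0   p[22]
#define FA    p[23]
#define PIO2  p[24]
#define VLO2  p[25]
#define VLCO2 p[26]
#define BTO2  p[27]
#define BTCO2 p[28]
#define BBO2  p[29]
#define BBCO2 p[30]
#define HBCAP p[31]
#define SOLO2 p[32]
#define P50   p[33]
#define HILLN p[34]
#define CSL   p[35]
#define CINT  p[36]
#define MO2T  p[37]
#define MO2B  p[38]
#define VCO2T p[39]
#define VCO2B p[40]
#define QBRF  p[41]
#define GC    p[42]
#define BC    p[43]
#define GP    p[44]
#define BP    p[45]
#define HVRA  p[46]
#define HVRP0 p[47]
#define HVRT  p[48]
#define VEFL  p[49]
#define TAUVE p[50]
#define TAUCO p[51]
#define PCRIT p[52]
#define WWID  p[53]
#define TAUD  p[54]
#define PM    p[55]
#define TRIG  p[56]

void overdose_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static double o2sat(double po2)
{
    double x;
    if (po2 <= 0.0) return 0.0;
    x = pow(po2 / P50, HILLN);
    return x / (1.0 + x);
}

static double o2c(double po2)
{
    if (po2 < 0.0) po2 = 0.0;
    return HBCAP * o2sat(po2) + SOLO2 * po2;
}

static double co2c(double pco2)
{
    if (pco2 < 0.0) pco2 = 0.0;
    return CSL * pco2 + CINT;
}

static double metab_scale(double po2)
{
    if (po2 <= 0.0) return 0.0;
    if (po2 >= PM) return 1.0;
    return po2 / PM;
}

void overdose_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    double Cpa, Cpn, free_r, Ra, Rn, eff, dep;
    double VE, CO, VA, Qbr, Qt;
    double CaO2, CaCO2, CtO2, CbrO2, CtCO2, CbrCO2, CvO2, CvCO2;
    double mt, mbr, mo2t, vco2t;
    double central, hyp, peripheral, vet, w;

    /* --- pharmacokinetics --------------------------------------- */
    ydot[0] = -(CLa + Qa) / V1a * y[0] + Qa / V2a * y[1];
    ydot[1] = Qa / V1a * y[0] - Qa / V2a * y[1];
    Cpa = y[0] * CONVA;            /* nM */
    ydot[2] = KE0A * (Cpa - y[2]);

    ydot[3] = -KAN * y[3];
    ydot[4] = KAN * y[3] - (CLn + Qn) / V1n * y[4] + Qn / V2n * y[5];
    ydot[5] = Qn / V1n * y[4] - Qn / V2n * y[5];
    Cpn = y[4] * CONVN;
    ydot[6] = KE0N * (Cpn - y[6]);

    /* --- competitive receptor binding ---------------------------- */
    Ra = y[7]; Rn = y[8];
    if (Ra < 0.0) Ra = 0.0;
    if (Ra > 1.0) Ra = 1.0;
    if (Rn < 0.0) Rn = 0.0;
    if (Rn > 1.0) Rn = 1.0;
    free_r = 1.0 - Ra - Rn;
    if (free_r < 0.0) free_r = 0.0;
    ydot[7] = KONA * fmax(y[2], 0.0) * free_r - KOFFA * Ra;
    ydot[8] = KONN * fmax(y[6], 0.0) * free_r - KOFFN * Rn;

    /* --- occupancy -> ventilatory depression --------------------- */
    if (PDFORM < 0.5) {
        eff = Ra;
    } else {
        double rg = pow(Ra, PDGAM), r50g = pow(PDR50, PDGAM);
        eff = rg / (rg + r50g) * (1.0 + r50g);
    }
    dep = PDFLOOR + (1.0 - PDFLOOR) * (1.0 - eff);
    if (dep < 0.0) dep = 0.0;
    if (dep > 1.0) dep = 1.0;

    /* --- cardiorespiratory model --------------------------------- */
    VE = fmax(y[15], 0.0);
    CO = fmax(y[16], 1e-9);
    VA = FA * VE;
    Qbr = QBRF * CO;
    Qt = CO - Qbr;

    CaO2 = o2c(y[9]);
    CaCO2 = co2c(y[10]);
    CtO2 = o2c(y[11]);
    CbrO2 = o2c(y[13]);
    CtCO2 = co2c(y[12]);
    CbrCO2 = co2c(y[14]);
    CvO2 = (Qbr * CbrO2 + Qt * CtO2) / CO;
    CvCO2 = (Qbr * CbrCO2 + Qt * CtCO2) / CO;

    mt = metab_scale(y[11]);
    mbr = metab_scale(y[13]);
    mo2t = MO2T * mt;        /* MO2T, VCO2T are the non-brain shares */
    vco2t = VCO2T * mt;

    ydot[9]  = (VA * (PIO2 - y[9]) - 863.0 * CO * (CaO2 - CvO2)) / VLO2;
    ydot[10] = (-VA * y[10] + 863.0 * CO * (CvCO2 - CaCO2)) / VLCO2;
    ydot[11] = (Qt * (CaO2 - CtO2) - mo2t) / BTO2;
    ydot[12] = (Qt * (CaCO2 - CtCO2) + vco2t) / BTCO2;
    ydot[13] = (Qbr * (CaO2 - CbrO2) - MO2B * mbr) / BBO2;
    ydot[14] = (Qbr * (CaCO2 - CbrCO2) + VCO2B * mbr) / BBCO2;

    central = GC * fmax(y[14] - BC, 0.0);
    hyp = 1.0 + HVRA * exp(-(y[9] - HVRP0) / HVRT);
    peripheral = GP * fmax(y[10] - BP, 0.0) * hyp;
    vet = dep * (central + peripheral);
    if (vet < VEFL) vet = VEFL;
    ydot[15] = (vet - y[15]) / TAUVE;

    w = 1.0 / (1.0 + exp((PCRIT - y[9]) / WWID));
    ydot[16] = w * (CO0 - y[16]) / TAUCO - (1.0 - w) * y[16] / TAUD;

    if (y[9] <= 0.0 && ydot[9] < 0.0) ydot[9] = 0.0;
    if (y[11] <= 0.0 && ydot[11] < 0.0) ydot[11] = 0.0;
    if (y[13] <= 0.0 && ydot[13] < 0.0) ydot[13] = 0.0;
}

/* root: ventilation crossing the naloxone trigger level */
void overdose_root(int *neq, double *t, double *y, int *ng, double *gout,
                   double *out, int *ip)
{
    gout[0] = y[15] - TRIG;
}

static const R_CMethodDef cMethods[] = {
    {"overdose_init",   (DL_FUNC) &overdose_init,   1},
    {"overdose_derivs", (DL_FUNC) &overdose_derivs, 6},
    {"overdose_root",   (DL_FUNC) &overdose_root,   7},
    {NULL, NULL, 0}
};

void R_init_naloxsim(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
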