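/* Compiled right-hand sides for the whole-body iron distribution model,
 * in the deSolve compiled-model convention (initializer + derivative
 * functions resolved by name from this shared object).
 *
 * Units: concentrations M, volumes L, time days; all reaction fluxes are
 * computed in extensive units (mol/day) because reactions cross
 * compartments, then divided by the home compartment volume.  The two
 * "outside" pools are tracked in amount (mol): excretion has no volume.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

static double parms[27];

#define V_BM        parms[0]
#define V_DUO       parms[1]
#define V_LIVER     parms[2]
#define V_PLASMA    parms[3]
#define V_RBC       parms[4]
#define V_REST      parms[5]
#define V_SPLEEN    parms[6]
#define kInDuo      parms[7]
#define kInLiver    parms[8]
#define kInRBC      parms[9]
#define kInRest     parms[10]
#define kInBM       parms[11]
#define kDuoLoss    parms[12]
#define kRestOut    parms[13]
#define kBMSpleen   parms[14]
#define vRBCSpleen  parms[15]
#define VDuoNTBI    parms[16]
#define VLiverNTBI  parms[17]
#define VSpleenNTBI parms[18]
#define VRestNTBI   parms[19]
#define Km          parms[20]
#define Ki          parms[21]
#define vDiet       parms[22]
#define kNTBI_Fe1Tf parms[23]
#define kFe1Tf_Fe2Tf parms[24]
#define kHepSyn     parms[25]
#define kHepDeg     parms[26]

void ferrokin_initmod(void (*odeparms)(int *, double *))
{
    int n = 27;
    odeparms(&n, parms);
}

/* Ferroportin export, saturable with competitive inhibition by the
 * isotopic twin and non-competitive inhibition by hepcidin:
 *   v = V * Volume * S / ((Km + S + Ic) * (1 + Hep/Ki))        */
static double fpn(double Vmax, double vol, double S, double Ic, double hepfac)
{
    return Vmax * vol * S / ((Km + S + Ic) * hepfac);
}

/* Full system with the radioactive tracer.  State layout (23):
 *  0 FeBM    1 FeBM*   2 FeDuo    3 FeDuo*   4 FeLiver  5 FeLiver*
 *  6 FeSpleen 7 FeSpleen* 8 FeRBC 9 FeRBC*  10 FeRest  11 FeRest*
 * 12 FeOutside (mol) 13 FeOutside* (mol)
 * 14 NTBI  15 NTBI*  16 Tf  17 Fe1Tf  18 Fe1Tf*  19 Fe2Tf
 * 20 Fe2Tf* (mixed)  21 Fe2Tf**  22 Hepcidin                     */
void ferrokin_deriv_tracer(int *neq, double *t, double *y, double *ydot,
                           double *yout, int *ip)
{
    double hepfac = 1.0 + y[22] / Ki;
    double Vp = V_PLASMA;

    /* ferroportin export to plasma NTBI, unlabeled / labeled pairs */
    double fpDuo    = fpn(VDuoNTBI,    V_DUO,    y[2],  y[3],  hepfac);
    double fpDuoT   = fpn(VDuoNTBI,    V_DUO,    y[3],  y[2],  hepfac);
    double fpLiv    = fpn(VLiverNTBI,  V_LIVER,  y[4],  y[5],  hepfac);
    double fpLivT   = fpn(VLiverNTBI,  V_LIVER,  y[5],  y[4],  hepfac);
    double fpSpl    = fpn(VSpleenNTBI, V_SPLEEN, y[6],  y[7],  hepfac);
    double fpSplT   = fpn(VSpleenNTBI, V_SPLEEN, y[7],  y[6],  hepfac);
    double fpRest   = fpn(VRestNTBI,   V_REST,   y[10], y[11], hepfac);
    double fpRestT  = fpn(VRestNTBI,   V_REST,   y[11], y[10], hepfac);

    /* irreversible transferrin binding in plasma, all label combinations */
    double bNTf   = kNTBI_Fe1Tf  * y[14] * y[16] * Vp;  /* NTBI  + Tf     -> Fe1Tf   */
    double bNtTf  = kNTBI_Fe1Tf  * y[15] * y[16] * Vp;  /* NTBI* + Tf     -> Fe1Tf*  */
    double bNF1   = kFe1Tf_Fe2Tf * y[14] * y[17] * Vp;  /* NTBI  + Fe1Tf  -> Fe2Tf   */
    double bNF1t  = kFe1Tf_Fe2Tf * y[14] * y[18] * Vp;  /* NTBI  + Fe1Tf* -> Fe2Tf*  */
    double bNtF1  = kFe1Tf_Fe2Tf * y[15] * y[17] * Vp;  /* NTBI* + Fe1Tf  -> Fe2Tf*  */
    double bNtF1t = kFe1Tf_Fe2Tf * y[15] * y[18] * Vp;  /* NTBI* + Fe1Tf* -> Fe2Tf** */

    /* transferrin-mediated import: first order in each Tf-iron species,
     * one rate constant per receiving organ; Tf returns to plasma */
    double ksum = kInDuo + kInLiver + kInRest + kInBM;
    double impU = (y[17] + 2.0 * y[19] + y[20]) * Vp;  /* unlabeled iron per unit kIn */
    double impL = (y[18] + y[20] + 2.0 * y[21]) * Vp;  /* labeled iron per unit kIn   */

    /* erythroid cycling and losses, first order mass action */
    double bmRBC   = kInRBC    * y[0]  * V_BM;
    double bmRBCt  = kInRBC    * y[1]  * V_BM;
    double bmSpl   = kBMSpleen * y[0]  * V_BM;
    double bmSplT  = kBMSpleen * y[1]  * V_BM;
    double rbcSpl  = vRBCSpleen * y[8] * V_RBC;
    double rbcSplT = vRBCSpleen * y[9] * V_RBC;
    double duoLoss  = kDuoLoss * y[2]  * V_DUO;
    double duoLossT = kDuoLoss * y[3]  * V_DUO;
    double restOut  = kRestOut * y[10] * V_REST;
    double restOutT = kRestOut * y[11] * V_REST;

    double diet = vDiet * V_DUO;

    ydot[0]  = (kInBM * impU - bmRBC - bmSpl) / V_BM;
    ydot[1]  = (kInBM * impL - bmRBCt - bmSplT) / V_BM;
    ydot[2]  = (diet + kInDuo * impU - fpDuo - duoLoss) / V_DUO;
    ydot[3]  = (kInDuo * impL - fpDuoT - duoLossT) / V_DUO;
    ydot[4]  = (kInLiver * impU - fpLiv) / V_LIVER;
    ydot[5]  = (kInLiver * impL - fpLivT) / V_LIVER;
    ydot[6]  = (bmSpl + rbcSpl - fpSpl) / V_SPLEEN;
    ydot[7]  = (bmSplT + rbcSplT - fpSplT) / V_SPLEEN;
    ydot[8]  = (bmRBC - rbcSpl) / V_RBC;
    ydot[9]  = (bmRBCt - rbcSplT) / V_RBC;
    ydot[10] = (kInRest * impU - fpRest - restOut) / V_REST;
    ydot[11] = (kInRest * impL - fpRestT - restOutT) / V_REST;
    ydot[12] = duoLoss + restOut;       /* amount pools */
    ydot[13] = duoLossT + restOutT;
    ydot[14] = (fpDuo + fpLiv + fpSpl + fpRest - bNTf - bNF1 - bNF1t) / Vp;
    ydot[15] = (fpDuoT + fpLivT + fpSplT + fpRestT - bNtTf - bNtF1 - bNtF1t) / Vp;
    ydot[16] = (-bNTf - bNtTf
                + ksum * (y[17] + y[18] + y[19] + y[20] + y[21]) * Vp) / Vp;
    ydot[17] = (bNTf - bNF1 - bNtF1 - ksum * y[17] * Vp) / Vp;
    ydot[18] = (bNtTf - bNF1t - bNtF1t - ksum * y[18] * Vp) / Vp;
    ydot[19] = (bNF1 - ksum * y[19] * Vp) / Vp;
    ydot[20] = (bNF1t + bNtF1 - ksum * y[20] * Vp) / Vp;
    ydot[21] = (bNtF1t - ksum * y[21] * Vp) / Vp;
    ydot[22] = kHepSyn - kHepDeg * y[22];
}

/* Tracer-free system.  State layout (12):
 *  0 FeBM  1 FeDuo  2 FeLiver  3 FeSpleen  4 FeRBC  5 FeRest
 *  6 FeOutside (mol)  7 NTBI  8 Tf  9 Fe1Tf  10 Fe2Tf  11 Hepcidin */
void ferrokin_deriv_plain(int *neq, double *t, double *y, double *ydot,
                          double *yout, int *ip)
{
    double hepfac = 1.0 + y[11] / Ki;
    double Vp = V_PLASMA;

    double fpDuo  = fpn(VDuoNTBI,    V_DUO,    y[1], 0.0, hepfac);
    double fpLiv  = fpn(VLiverNTBI,  V_LIVER,  y[2], 0.0, hepfac);
    double fpSpl  = fpn(VSpleenNTBI, V_SPLEEN, y[3], 0.0, hepfac);
    double fpRest = fpn(VRestNTBI,   V_REST,   y[5], 0.0, hepfac);

    double bNTf = kNTBI_Fe1Tf  * y[7] * y[8] * Vp;
    double bNF1 = kFe1Tf_Fe2Tf * y[7] * y[9] * Vp;

    double ksum = kInDuo + kInLiver + kInRest + kInBM;
    double impU = (y[9] + 2.0 * y[10]) * Vp;

    double bmRBC   = kInRBC    * y[0] * V_BM;
    double bmSpl   = kBMSpleen * y[0] * V_BM;
    double rbcSpl  = vRBCSpleen * y[4] * V_RBC;
    double duoLoss = kDuoLoss * y[1] * V_DUO;
    double restOut = kRestOut * y[5] * V_REST;
    double diet = vDiet * V_DUO;

    ydot[0]  = (kInBM * impU - bmRBC - bmSpl) / V_BM;
    ydot[1]  = (diet + kInDuo * impU - fpDuo - duoLoss) / V_DUO;
    ydot[2]  = (kInLiver * impU - fpLiv) / V_LIVER;
    ydot[3]  = (bmSpl + rbcSpl - fpSpl) / V_SPLEEN;
    ydot[4]  = (bmRBC - rbcSpl) / V_RBC;
    ydot[5]  = (kInRest * impU - fpRest - restOut) / V_REST;
    ydot[6]  = duoLoss + restOut;
    ydot[7]  = (fpDuo + fpLiv + fpSpl + fpRest - bNTf - bNF1) / Vp;
    ydot[8]  = (-bNTf + ksum * (y[9] + y[10]) * Vp) / Vp;
    ydot[9]  = (bNTf - bNF1 - ksum * y[9] * Vp) / Vp;
    ydot[10] = (bNF1 - ksum * y[10] * Vp) / Vp;
    ydot[11] = kHepSyn - kHepDeg * y[11];
}

static const R_CMethodDef cMethods[] = {
    {"ferrokin_initmod",      (DL_FUNC) &ferrokin_initmod,      1},
    {"ferrokin_deriv_tracer", (DL_FUNC) &ferrokin_deriv_tracer, 6},
    {"ferrokin_deriv_plain",  (DL_FUNC) &ferrokin_deriv_plain,  6},
    {NULL, NULL, 0}
};

void R_init_ferrokin(DllInfo *dll)
{
    R_registerRoutines(dll, cMethods, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
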