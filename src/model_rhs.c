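/* Compiled right-hand side of the kinetochore phosphatase network for
 * deSolve.  Kept in exact correspondence with the R implementation
 * (derivs_fast); the parameter vector is packed by pack_parms() on the R
 * side: 15 rate constants, 6 totals, 3 kinase activities, the
 * catalytic-dead flag, the clamp flag and the clamp value.
 */
#include <R.h>

static double parms[27];

#define kbPP1        parms[0]
#define kdPP1        parms[1]
#define kbPP2A       parms[2]
#define kdPP2A       parms[3]
#define kbBUBR1      parms[4]
#define kdBUBR1      parms[5]
#define kpBUBR1      parms[6]
#define kpBUBR1free  parms[7]
#define kdpBUBR1     parms[8]
#define kpMELT       parms[9]
#define kdpMELT      parms[10]
#define kpRVSF       parms[11]
#define kdpRVSF      parms[12]
#define kpNDC80      parms[13]
#define kdpNDC80     parms[14]
#define PP1tot       parms[15]
#define PP2Atot      parms[16]
#define MELTtot      parms[17]
#define BUBR1tot     parms[18]
#define RVSFtot      parms[19]
#define NDC80tot     parms[20]
#define MPS1         parms[21]
#define AurB         parms[22]
#define CDK1         parms[23]
#define DEADPP2A     parms[24]
#define CLAMPED      parms[25]
#define CLAMPVAL     parms[26]

void kp_initmod(void (*odeparms)(int *, double *))
{
    int n = 27;
    odeparms(&n, parms);
}

/* y: PP1act, PP2Aact, pBUBR1free, pBUBR1_PP2A, pMELT, pMELT_BUBR1,
 *    pMELT_pBUBR1, pRVSF, pNDC80 */
void kp_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int clamped = CLAMPED > 0.5;
    double PP1act = y[0];
    double PP2Aact = clamped ? CLAMPVAL : y[1];
    double pBf = y[2], pBP = y[3], pM = y[4], pMB = y[5], pMpB = y[6];
    double pR = y[7], pN = y[8];

    double cplx = clamped ? 0.0 : PP2Aact;   /* PP2Aact as complex */
    double PP1free  = PP1tot - PP1act;
    double PP2Afree = PP2Atot - cplx - pBP;
    double Mfree = MELTtot - pM - pMB - pMpB - cplx;
    double Bfree = BUBR1tot - pBf - pMB - pMpB - pBP - cplx;
    double Rfree = RVSFtot - pR - PP1act;
    double Nfree = NDC80tot - pN;

    double pp = (DEADPP2A > 0.5) ? PP1act : PP1act + PP2Aact;
    double on = clamped ? 0.0 : 1.0;   /* BUBR1-side complex turnover */

    ydot[0] = kbPP1 * Rfree * PP1free - kdPP1 * PP1act;

    ydot[1] = clamped ? 0.0
        : kbPP2A * pMpB * PP2Afree + kbBUBR1 * pBP * pM
          - kdPP2A * PP2Aact - kdBUBR1 * PP2Aact;

    ydot[2] = kdBUBR1 * pMpB + kdPP2A * pBP + kpBUBR1free * Bfree * CDK1
              - kbBUBR1 * pBf * pM - kbPP2A * pBf * PP2Afree;

    ydot[3] = kbPP2A * pBf * PP2Afree + on * kdBUBR1 * PP2Aact
              - kdPP2A * pBP - on * kbBUBR1 * pBP * pM;

    ydot[4] = kdBUBR1 * pMB + kdBUBR1 * pMpB + on * kdBUBR1 * PP2Aact
              + kpMELT * Mfree * MPS1
              - kbBUBR1 * Bfree * pM - kbBUBR1 * pBf * pM
              - on * kbBUBR1 * pBP * pM - kdpMELT * pM * pp;

    ydot[5] = kbBUBR1 * Bfree * pM + kdpBUBR1 * pMpB * pp
              - kdBUBR1 * pMB - kpBUBR1 * pMB * CDK1;

    ydot[6] = kbBUBR1 * pBf * pM + kpBUBR1 * pMB * CDK1
              + on * kdPP2A * PP2Aact - kdBUBR1 * pMpB
              - kdpBUBR1 * pMpB * pp - on * kbPP2A * pMpB * PP2Afree;

    ydot[7] = kpRVSF * Rfree * AurB - kdpRVSF * pR * pp;
    ydot[8] = kpNDC80 * Nfree * AurB - kdpNDC80 * pN * pp;
}
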