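/* Two-chemical PBPK right-hand side for DPHP (parent diester) and MPHP
 * (monoester), solved as a delay differential system.
 *
 * Compartment conventions (masses, mg):
 *  - chemical in stomach / GI lumen is split at intake into a hepatic-route
 *    pool, a lymphatic-route pool, and an unabsorbed fraction passing
 *    directly to the bowel (faeces);
 *  - hepatic-route uptake (stomach + GI permeability) reaches the gut wall
 *    after a transit delay Gutlag; lymphatic-route uptake reaches the
 *    thoracic-duct pool after Lymphlag and empties into venous blood as a
 *    first-order process (K1Lymph), bypassing first-pass metabolism;
 *  - biliary transfer from liver back to the GI lumen is first order with a
 *    transport delay Bilelag (enterohepatic recirculation), competing with
 *    first-order faecal loss from the GI lumen;
 *  - distribution is flow-limited; only the unbound fraction fu of arterial
 *    blood exchanges with tissues, the bound remainder passes through to
 *    venous blood;
 *  - DPHP is metabolised to MPHP in gut wall and liver (whole-organ
 *    intrinsic clearances applied to the venous-equilibrated tissue
 *    concentration: binding limits delivery, not the metabolic rate, so
 *    first-pass extraction of newly absorbed chemical is near-complete),
 *    MPHP in liver only, splitting into OH-/cx-/other metabolites;
 *    OH- and cx-MPHP occupy central pools eliminated first order to urine.
 *
 * All states start at zero, so lagged values before t = 0 are zero.
 */
#include <R.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPAR 56
static double p[NPAR];

/* parameter indices (match R side: dphpk_parms_vector) */
#define Vart    p[0]
#define Vven    p[1]
#define Vgu     p[2]
#define Vli     p[3]
#define Vfa     p[4]
#define Vspd    p[5]
#define Vrpd    p[6]
#define QC      p[7]
#define Qfa     p[8]
#define Qspd    p[9]
#define Qrpd    p[10]
#define Qgu     p[11]
#define QHe     p[12]
#define Qshunt  p[13]
#define fuD     p[14]
#define fuM     p[15]
#define PfaD    p[16]
#define PliD    p[17]
#define PspdD   p[18]
#define PrpdD   p[19]
#define PguD    p[20]
#define PfaM    p[21]
#define PliM    p[22]
#define PspdM   p[23]
#define PrpdM   p[24]
#define PguM    p[25]
#define CLmet_li_D p[26]
#define CLmet_gu_D p[27]
#define CLmet_li_M p[28]
#define kmax    p[29]
#define kmin    p[30]
#define tau_ge  p[31]
#define BPERM   p[32]
#define GIPERM_ p[33]
#define BPERML  p[34]
#define GIPERML p[35]
#define kGa     p[36]
#define K1Ly    p[37]
#define k1Dgut  p[38]
#define k1Mgut  p[39]
#define k1Dliv  p[40]
#define k1Mliv  p[41]
#define K1MOH   p[42]
#define K1cx    p[43]
#define FracOH  p[44]
#define Fraccx  p[45]
#define Gutlag  p[46]
#define Lymphlag p[47]
#define Bilelag p[48]
#define doserate p[49]
#define DRINKT  p[50]
#define FDH     p[51]
#define FDL     p[52]
#define rMD     p[53]
#define rOHM    p[54]
#define rcxM    p[55]

/* state indices */
#define iAStH 0
#define iAGIH 1
#define iAStL 2
#define iAGIL 3
#define iAupT 4
#define iAlyT 5
#define iAly  6
#define iAbiT 7
#define iAgu  8
#define iAli  9
#define iAfa  10
#define iAspd 11
#define iArpd 12
#define iAart 13
#define iAven 14
#define iAbw  15
#define iMGI  16
#define iMbiT 17
#define iMgu  18
#define iMli  19
#define iMfa  20
#define iMspd 21
#define iMrpd 22
#define iMart 23
#define iMven 24
#define iMbw  25
#define iAOH  26
#define iAcx  27
#define iUOH  28
#define iUcx  29
#define iMoth 30

void dphpk_init(void (*odeparms)(int *, double *))
{
    int n = NPAR;
    odeparms(&n, p);
}

static void lagvalue(double T, int *nr, int N, double *ytau)
{
    typedef void lagfun(double, int *, int, double *);
    static lagfun *fun = NULL;
    if (fun == NULL)
        fun = (lagfun *) R_GetCCallable("deSolve", "lagvalue");
    fun(T, nr, N, ytau);
}

/* fetch a single lagged state; before t = 0 the history is the (zero)
 * initial state; zero lag means the current state (ODE reduction) */
static double lagstate(double t, double lag, int idx, double *y)
{
    if (lag <= 0.0)
        return y[idx];
    double tl = t - lag;
    if (tl <= 0.0)
        return 0.0;
    double yl;
    int nr = idx;
    lagvalue(tl, &nr, 1, &yl);
    return yl;
}

void dphpk_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double tt = *t;

    double drink = (tt < DRINKT) ? doserate : 0.0;
    double kge = kmin + (kmax - kmin) * exp(-tt / tau_ge);

    /* hepatic-route uptake flux (current and lagged by Gutlag) */
    double u  = BPERM * y[iAStH] + GIPERM_ * y[iAGIH];
    double uL = BPERM * lagstate(tt, Gutlag, iAStH, y)
              + GIPERM_ * lagstate(tt, Gutlag, iAGIH, y);

    /* lymphatic-route uptake flux (current and lagged by Lymphlag) */
    double ul  = BPERML * y[iAStL] + GIPERML * y[iAGIL];
    double ulL = BPERML * lagstate(tt, Lymphlag, iAStL, y)
               + GIPERML * lagstate(tt, Lymphlag, iAGIL, y);

    /* biliary outflow = first-order liver uptake, Bilelag hours ago */
    double bileD = k1Dliv * lagstate(tt, Bilelag, iAli, y);
    double bileM = k1Mliv * lagstate(tt, Bilelag, iMli, y);

    double QliT = QHe + Qgu;

    /* DPHP concentrations */
    double CaD    = y[iAart] / Vart;
    double CvenD  = y[iAven] / Vven;
    double CvguD  = y[iAgu] / (Vgu * PguD);
    double CvliD  = y[iAli] / (Vli * PliD);
    double CvfaD  = y[iAfa] / (Vfa * PfaD);
    double CvspdD = y[iAspd] / (Vspd * PspdD);
    double CvrpdD = y[iArpd] / (Vrpd * PrpdD);

    /* MPHP concentrations */
    double CaM    = y[iMart] / Vart;
    double CvenM  = y[iMven] / Vven;
    double CvguM  = y[iMgu] / (Vgu * PguM);
    double CvliM  = y[iMli] / (Vli * PliM);
    double CvfaM  = y[iMfa] / (Vfa * PfaM);
    double CvspdM = y[iMspd] / (Vspd * PspdM);
    double CvrpdM = y[iMrpd] / (Vrpd * PrpdM);

    double rGutMetD = CLmet_gu_D * CvguD; /* gut-wall DPHP -> MPHP */
    double rLivMetD = CLmet_li_D * CvliD; /* hepatic DPHP -> MPHP  */
    double rLivMetM = CLmet_li_M * CvliM; /* hepatic MPHP -> OH/cx/other */

    /* --- DPHP --- */
    ydot[iAStH] = FDH * drink - kge * y[iAStH] - BPERM * y[iAStH];
    ydot[iAGIH] = kge * y[iAStH] + bileD - GIPERM_ * y[iAGIH]
                - k1Dgut * y[iAGIH];
    ydot[iAStL] = FDL * drink - kge * y[iAStL] - BPERML * y[iAStL];
    ydot[iAGIL] = kge * y[iAStL] - GIPERML * y[iAGIL];
    ydot[iAupT] = u - uL;
    ydot[iAlyT] = ul - ulL;
    ydot[iAly]  = ulL - K1Ly * y[iAly];
    ydot[iAbiT] = k1Dliv * y[iAli] - bileD;
    ydot[iAgu]  = uL + Qgu * (fuD * CaD - CvguD) - rGutMetD;
    ydot[iAli]  = QHe * fuD * CaD + Qgu * CvguD - QliT * CvliD
                - rLivMetD - k1Dliv * y[iAli];
    ydot[iAfa]  = Qfa * (fuD * CaD - CvfaD);
    ydot[iAspd] = Qspd * (fuD * CaD - CvspdD);
    ydot[iArpd] = Qrpd * (fuD * CaD - CvrpdD);
    ydot[iAart] = QC * (CvenD - CaD);
    ydot[iAven] = Qfa * CvfaD + Qspd * CvspdD + Qrpd * CvrpdD
                + QliT * CvliD + (1.0 - fuD) * CaD * QC
                + fuD * CaD * Qshunt + K1Ly * y[iAly] - QC * CvenD;
    ydot[iAbw]  = (1.0 - FDH - FDL) * drink + k1Dgut * y[iAGIH];

    /* --- MPHP --- */
    ydot[iMGI]  = bileM - kGa * y[iMGI] - k1Mgut * y[iMGI];
    ydot[iMbiT] = k1Mliv * y[iMli] - bileM;
    ydot[iMgu]  = kGa * y[iMGI] + rGutMetD * rMD
                + Qgu * (fuM * CaM - CvguM);
    ydot[iMli]  = rLivMetD * rMD + QHe * fuM * CaM + Qgu * CvguM
                - QliT * CvliM - rLivMetM - k1Mliv * y[iMli];
    ydot[iMfa]  = Qfa * (fuM * CaM - CvfaM);
    ydot[iMspd] = Qspd * (fuM * CaM - CvspdM);
    ydot[iMrpd] = Qrpd * (fuM * CaM - CvrpdM);
    ydot[iMart] = QC * (CvenM - CaM);
    ydot[iMven] = Qfa * CvfaM + Qspd * CvspdM + Qrpd * CvrpdM
                + QliT * CvliM + (1.0 - fuM) * CaM * QC
                + fuM * CaM * Qshunt - QC * CvenM;
    ydot[iMbw]  = k1Mgut * y[iMGI];

    /* --- second-order metabolites --- */
    ydot[iAOH]  = FracOH * rLivMetM * rOHM - K1MOH * y[iAOH];
    ydot[iAcx]  = Fraccx * rLivMetM * rcxM - K1cx * y[iAcx];
    ydot[iUOH]  = K1MOH * y[iAOH];
    ydot[iUcx]  = K1cx * y[iAcx];
    ydot[iMoth] = (1.0 - FracOH - Fraccx) * rLivMetM;
}
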