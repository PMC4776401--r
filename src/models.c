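/* Right-hand sides for the three glucose/FFA minimal-model variants,
 * in the deSolve compiled-model convention (initfunc/initforc/derivs).
 *
 * Insulin enters as a forcing function, linearly interpolated by the
 * integrator between the measured samples and clamped outside the
 * sampled window.  MOD 3's delayed insulin lookups are realised on the
 * R side by passing time-shifted copies of the insulin record as two
 * separate forcings, so no delay-differential machinery is needed.
 */

#include <R.h>
#include <math.h>

/* ---- shared meal rate-of-appearance (Ra) forms ---------------------- */

/* log-normal-like Ra: 0 at t <= 0, Delta/(t*sigma) exp(-ln(t/m)^2/(2 sigma^2)) */
static double ra_lognormal(double t, double Delta, double m, double sigma)
{
    double z;
    if (t <= 0.0 || Delta == 0.0)
        return 0.0;
    z = log(t / m);
    return Delta / (t * sigma) * exp(-(z * z) / (2.0 * sigma * sigma));
}

/* Rayleigh-like Ra: phi*t/tau^2 exp(-t^2/(2 tau^2)) */
static double ra_rayleigh(double t, double phi, double tau)
{
    if (t < 0.0 || phi == 0.0)
        return 0.0;
    return phi * t / (tau * tau) * exp(-(t * t) / (2.0 * tau * tau));
}

/* Ra parameter block appended to every model's parms vector:
 *   [0] glucose Ra type: 0 none, 1 log-normal-like, 2 Rayleigh-like
 *   [1..3] Delta_G/phi_G, m_G/tau_G, sigma_G (unused slots ignored)
 *   [4] FFA Ra type: 0 none, 1 log-normal-like with lag
 *   [5..8] Delta_F, m_F, sigma_F, t_0F
 */
#define N_RA 9

static double ra_glucose(double t, const double *ra)
{
    int type = (int) ra[0];
    if (type == 1)
        return ra_lognormal(t, ra[1], ra[2], ra[3]);
    if (type == 2)
        return ra_rayleigh(t, ra[1], ra[2]);
    return 0.0;
}

static double ra_ffa(double t, const double *ra)
{
    if ((int) ra[4] == 1)
        return ra_lognormal(t - ra[8], ra[5], ra[6], ra[7]);
    return 0.0;
}

/* transient solver excursions can push X slightly negative; Hill terms
 * are evaluated with X clamped at 0 */
static double clamp0(double x)
{
    return x > 0.0 ? x : 0.0;
}

/* ---- MOD 1: insulin-action model, insulin-stimulated FFA clearance -- */

#define N_P1 (12 + N_RA)
static double p1[N_P1];
static double forc1[1];

#define P1_S_G    p1[0]
#define P1_G_b    p1[1]
#define P1_S_I    p1[2]
#define P1_C_x    p1[3]
#define P1_I_bx   p1[4]
#define P1_l_0    p1[5]
#define P1_l_2    p1[6]
#define P1_X_2    p1[7]
#define P1_A_lipo p1[8]
#define P1_C_f    p1[9]
#define P1_K_Cl   p1[10]
#define P1_A_Cl   p1[11]

void ffamm_init_mod1(void (*odeparms)(int *, double *))
{
    int n = N_P1;
    odeparms(&n, p1);
}

void ffamm_forc_mod1(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc1);
}

void ffamm_derivs_mod1(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double G = y[0], X = y[1], F = y[2];
    double I = forc1[0];
    double Xc = clamp0(X);
    double hl = pow(Xc / P1_X_2, P1_A_lipo);
    double hc = pow(Xc / P1_K_Cl, P1_A_Cl);

    ydot[0] = P1_S_G * P1_G_b - (P1_S_G + P1_S_I * X) * G
        + ra_glucose(*t, p1 + 12);
    ydot[1] = P1_C_x * (I - X - P1_I_bx);
    ydot[2] = P1_l_0 + P1_l_2 / (1.0 + hl)
        - P1_C_f * (1.0 + hc / (1.0 + hc)) * F
        + ra_ffa(*t, p1 + 12);
}

/* ---- MOD 2: insulin-action model, constant FFA clearance ------------ */

#define N_P2 (10 + N_RA)
static double p2[N_P2];
static double forc2[1];

#define P2_S_G  p2[0]
#define P2_G_b  p2[1]
#define P2_S_I  p2[2]
#define P2_C_x  p2[3]
#define P2_I_bx p2[4]
#define P2_l_0  p2[5]
#define P2_l_2  p2[6]
#define P2_X_2  p2[7]
#define P2_A_l  p2[8]
#define P2_C_f0 p2[9]

void ffamm_init_mod2(void (*odeparms)(int *, double *))
{
    int n = N_P2;
    odeparms(&n, p2);
}

void ffamm_forc_mod2(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc2);
}

void ffamm_derivs_mod2(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double G = y[0], X = y[1], F = y[2];
    double I = forc2[0];
    double Xc = clamp0(X);
    double hl = pow(Xc / P2_X_2, P2_A_l);

    ydot[0] = P2_S_G * P2_G_b - (P2_S_G + P2_S_I * X) * G
        + ra_glucose(*t, p2 + 10);
    ydot[1] = P2_C_x * (I - X - P2_I_bx);
    ydot[2] = P2_l_0 + P2_l_2 / (1.0 + hl) - P2_C_f0 * F
        + ra_ffa(*t, p2 + 10);
}

/* ---- MOD 3: FFA only, delayed plasma insulin acts directly ---------- */

#define N_P3 (9 + N_RA)
static double p3[N_P3];
/* forcings: [0] I(t - t_DelayLip), [1] I(t - t_DelayRem) */
static double forc3[2];

#define P3_V_m_Lip p3[0]
#define P3_K_Lip   p3[1]
#define P3_h_lip   p3[2]
#define P3_k_Rem   p3[3]
#define P3_V_m_Rem p3[4]
#define P3_K_Rem   p3[5]
#define P3_h_Rem   p3[6]
/* p3[7], p3[8] reserved (delays live on the R side) */

void ffamm_init_mod3(void (*odeparms)(int *, double *))
{
    int n = N_P3;
    odeparms(&n, p3);
}

void ffamm_forc_mod3(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc3);
}

void ffamm_derivs_mod3(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double F = y[0];
    double Ilip = clamp0(forc3[0]);
    double Irem = clamp0(forc3[1]);
    double hr = pow(Irem, P3_h_Rem);
    double kr = pow(P3_K_Rem, P3_h_Rem);

    ydot[0] = P3_V_m_Lip / (1.0 + pow(Ilip / P3_K_Lip, P3_h_lip))
        - (P3_k_Rem + P3_V_m_Rem * hr / (kr + hr)) * F
        + ra_ffa(*t, p3 + 9);
}
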