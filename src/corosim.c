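/* Compiled right-hand side of the coupled cardiac-coronary model.
 *
 * State vector: [V_la, V_lv, V_art, V_ven,
 *                lumen volumes of LAD tree (n_lad),
 *                lumen volumes of LCX tree (n_lcx)].
 *
 * The coronary networks integrate one lumen volume per vessel; mid-node
 * pressures are recovered by inverting the sigmoidal diameter law, junction
 * pressures are eliminated by a local Kirchhoff balance, so volume is
 * conserved identically (inlet - outlet = d/dt total lumen volume).
 *
 * Parameter vector layout (doubles, 0-based):
 *   0 n_lad  1 n_lcx
 *   2 T      3 Tmax_LV  4 tau_LV  5 Tmax_LA  6 tau_LA  7 la_offset
 *   8 Ees_LAD  9 Ees_LCX  10 V_LV0  11 A_LV  12 B_LV
 *   13 Ees_LA  14 V_LA0  15 A_LA  16 B_LA
 *   17 F  18 dt_lcx  19 dt_bar
 *   20 R_ao  21 R_per  22 R_ven  23 R_mv
 *   24 C_art  25 C_ven  26 V_art0  27 V_ven0
 *   28 R_lad  29 R_lcx
 *   30 alpha  31 beta  32 gamma  33 EDV_prev
 *   34 mu  35 weight_floor
 *   36 lv_law (0 = shared-EDPVR closed form, 1 = compartment-resolved,
 *             2 = fixed-partition mixture: P = (F e1 + (1-F) e2) Pes + ...)
 *   37 ve_cross (0 = territory VE on its own clock, 1 = crossed clocks)
 *   38.. LAD tree block, then LCX tree block.
 * Tree block: [n_nodes, L[n], Ap[n], Bp[n], phip[n], Cp[n],
 *              upnode[n] (1-based), downnode[n] (0 = terminal)].
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define MAXVES 8192

static double *parms = NULL;
static R_xlen_t nparms = 0;

void initmod(void (*odeparms)(int *, double *))
{
    /* fetch deSolve's stored parameter object (arbitrary length) */
    SEXP (*get_gparms)(void) =
        (SEXP (*)(void)) R_GetCCallable("deSolve", "get_deSolve_gparms");
    SEXP gp = get_gparms();
    if (!Rf_isReal(gp))
        error("corosim: parameter vector must be numeric");
    parms = REAL(gp);
    nparms = XLENGTH(gp);
    if (nparms < 38)
        error("corosim: parameter vector too short");
}

/* compartment-resolved cavity pressure: both territories carry the same
 * pressure, volumes sum to V, and each compartment's EDPVR is evaluated at
 * its own volume scaled to the whole-ventricle equivalent (finite
 * diastolic stiffness of a relaxed territory).  Solved by safeguarded
 * Newton on the LAD compartment volume. */
static double lv_pressure_compartment(double V, double e1, double e2,
                                      double E1, double E2, double F,
                                      double V0, double A, double B)
{
    double V1 = F * V, lo = V - 2000.0, hi = 2000.0;
    int it;
    for (it = 0; it < 60; it++) {
        double x1 = V1 / F, x2 = (V - V1) / (1.0 - F);
        double p1 = e1 * (E1 / F) * (V1 - F * V0) +
                    (1.0 - e1) * A * expm1(B * (x1 - V0));
        double p2 = e2 * (E2 / (1.0 - F)) * ((V - V1) - (1.0 - F) * V0) +
                    (1.0 - e2) * A * expm1(B * (x2 - V0));
        double g = p1 - p2;
        double d1 = e1 * (E1 / F) + (1.0 - e1) * A * B * exp(B * (x1 - V0)) / F;
        double d2 = e2 * (E2 / (1.0 - F)) +
                    (1.0 - e2) * A * B * exp(B * (x2 - V0)) / (1.0 - F);
        double step;
        if (g > 0.0) hi = V1; else lo = V1;
        if (fabs(g) < 1e-10)
            return p1;
        step = g / (d1 + d2);
        V1 -= step;
        if (V1 <= lo || V1 >= hi)
            V1 = 0.5 * (lo + hi);
    }
    return e1 * (E1 / F) * (V1 - F * V0) +
           (1.0 - e1) * A * expm1(B * (V1 / F - V0));
}

static double act(double t, double Tmax, double tau, double T)
{
    t = fmod(t, T);
    if (t < 0) t += T;
    if (t < 1.5 * Tmax)
        return 0.5 * (sin(M_PI * t / Tmax - M_PI / 2.0) + 1.0);
    return 0.5 * exp(-(t - 1.5 * Tmax) / tau);
}

/* one coronary tree; returns inlet flow via *q_in, outlet via *q_out */
static void tree_rhs(const double *tb, int n, const double *vol,
                     double *dvol, double imp, double P_art, double P_ven,
                     double R_prox, double mu, double *q_in, double *q_out)
{
    static double Pmid[MAXVES], g[MAXVES], S[MAXVES], G[MAXVES];
    const double *L = tb + 1, *Ap = L + n, *Bp = Ap + n, *phip = Bp + n,
                 *Cp = phip + n, *up = Cp + n, *down = up + n;
    int nn = (int) tb[0];
    int i;

    if (n > MAXVES || nn > MAXVES)
        error("corosim: tree larger than compiled limit");

    for (i = 0; i < nn; i++) { S[i] = 0.0; G[i] = 0.0; }
    S[0] = P_art / R_prox;
    G[0] = 1.0 / R_prox;

    for (i = 0; i < n; i++) {
        double D = sqrt(4.0 * vol[i] / (M_PI * L[i]));
        double u = (0.5 * D - Bp[i]) / (Ap[i] - Bp[i]);
        double dP, Rh;
        if (u < 1e-12) u = 1e-12;
        if (u > 1.0 - 1e-12) u = 1.0 - 1e-12;
        dP = phip[i] + Cp[i] * tan(M_PI * u - M_PI / 2.0);
        Pmid[i] = dP + imp;
        Rh = 64.0 * mu * L[i] / (M_PI * D * D * D * D);
        g[i] = 1.0 / Rh;
        {
            int uu = (int) up[i] - 1;
            int dd = (int) down[i] - 1;
            S[uu] += g[i] * Pmid[i];
            G[uu] += g[i];
            if (dd >= 0) {
                S[dd] += g[i] * Pmid[i];
                G[dd] += g[i];
            }
        }
    }

    for (i = 0; i < nn; i++) S[i] /= G[i];   /* S now holds node pressures */

    *q_in = (P_art - S[0]) / R_prox;
    *q_out = 0.0;
    for (i = 0; i < n; i++) {
        int uu = (int) up[i] - 1;
        int dd = (int) down[i] - 1;
        double Qin = (S[uu] - Pmid[i]) * g[i];
        double Qout;
        if (dd >= 0) {
            Qout = (Pmid[i] - S[dd]) * g[i];
        } else {
            Qout = (Pmid[i] - P_ven) * g[i];
            *q_out += Qout;
        }
        dvol[i] = Qin - Qout;
    }
}

void derivs(int *neq, double *t, double *y, double *ydot, double *yout,
            int *ip)
{
    const double *p = parms;
    int n_lad = (int) p[0], n_lcx = (int) p[1];
    double T = p[2], Tmax_LV = p[3], tau_LV = p[4], Tmax_LA = p[5],
           tau_LA = p[6], la_offset = p[7];
    double Ees_LAD = p[8], Ees_LCX = p[9], V_LV0 = p[10], A_LV = p[11],
           B_LV = p[12];
    double Ees_LA = p[13], V_LA0 = p[14], A_LA = p[15], B_LA = p[16];
    double F = p[17], dt_lcx = p[18], dt_bar = p[19];
    double R_ao = p[20], R_per = p[21], R_ven = p[22], R_mv = p[23];
    double C_art = p[24], C_ven = p[25], V_art0 = p[26], V_ven0 = p[27];
    double R_lad = p[28], R_lcx = p[29];
    double alpha = p[30], beta = p[31], gamma_ = p[32], EDV_prev = p[33];
    double mu = p[34], wfloor = p[35];
    int lv_law = (int) p[36];
    int ve_cross = (int) p[37];
    const double *tb_lad = p + 38;
    const double *tb_lcx = tb_lad + 1 + 7 * n_lad;

    double V_la = y[0], V_lv = y[1], V_art = y[2], V_ven = y[3];
    double tt = *t;

    /* chamber pressures */
    double e1 = act(tt, Tmax_LV, tau_LV, T);
    double e2 = act(tt - dt_lcx, Tmax_LV, tau_LV, T);
    double w1 = Ees_LAD * e1, w2 = Ees_LCX * e2;
    double ped = A_LV * expm1(B_LV * (V_lv - V_LV0));
    double den = F * w2 + (1.0 - F) * w1;
    double P_lv;
    if (lv_law == 1) {
        P_lv = lv_pressure_compartment(V_lv, e1, e2, Ees_LAD, Ees_LCX, F,
                                       V_LV0, A_LV, B_LV);
    } else if (lv_law == 2) {
        double ebar = F * e1 + (1.0 - F) * e2;
        double Ebar = F * Ees_LAD + (1.0 - F) * Ees_LCX;
        P_lv = ebar * Ebar * (V_lv - V_LV0) + (1.0 - ebar) * ped;
    } else if (den < wfloor) {
        P_lv = ped;
    } else {
        P_lv = (w1 * w2 * (V_lv - V_LV0) +
                ped * (F * (1.0 - e1) * w2 + (1.0 - F) * (1.0 - e2) * w1)) /
               den;
    }

    double ela = act(tt + la_offset, Tmax_LA, tau_LA, T);
    double P_la = ela * Ees_LA * (V_la - V_LA0) +
                  (1.0 - ela) * A_LA * expm1(B_LA * (V_la - V_LA0));

    double P_art = (V_art - V_art0) / C_art;
    double P_ven = (V_ven - V_ven0) / C_ven;

    /* systemic flows */
    double q_ao = (P_lv >= P_art) ? (P_lv - P_art) / R_ao : 0.0;
    double q_mv = (P_la >= P_lv) ? (P_la - P_lv) / R_mv : 0.0;
    double q_per = (P_art - P_ven) / R_per;
    double q_ven = (P_ven - P_la) / R_ven;

    /* intramyocardial pressures.  ve_cross selects the pairing of the VE
     * clocks: direct (each territory's VE on its own activation clock) or
     * crossed (the LAD's VE follows the delayed LCX activation and vice
     * versa).  dt_bar delays both IMP clocks relative to the cavity
     * pressure. */
    double e_lad_imp, e_lcx_imp;
    if (ve_cross) {
        e_lad_imp = act(tt - dt_lcx - dt_bar, Tmax_LV, tau_LV, T);
        e_lcx_imp = act(tt - dt_bar, Tmax_LV, tau_LV, T);
    } else {
        e_lad_imp = act(tt - dt_bar, Tmax_LV, tau_LV, T);
        e_lcx_imp = act(tt - dt_lcx - dt_bar, Tmax_LV, tau_LV, T);
    }
    double cep = alpha * P_lv;
    double sip = gamma_ * (1.0 - V_lv / EDV_prev);
    double ve_lad = beta * Ees_LAD * e_lad_imp;
    double ve_lcx = beta * Ees_LCX * e_lcx_imp;
    double imp_lad = cep + ve_lad + sip;
    double imp_lcx = cep + ve_lcx + sip;

    double q_lad_in, q_lad_out, q_lcx_in, q_lcx_out;
    tree_rhs(tb_lad, n_lad, y + 4, ydot + 4, imp_lad, P_art, P_ven,
             R_lad, mu, &q_lad_in, &q_lad_out);
    tree_rhs(tb_lcx, n_lcx, y + 4 + n_lad, ydot + 4 + n_lad, imp_lcx,
             P_art, P_ven, R_lcx, mu, &q_lcx_in, &q_lcx_out);

    ydot[0] = q_ven - q_mv;
    ydot[1] = q_mv - q_ao;
    ydot[2] = q_ao - q_per - q_lad_in - q_lcx_in;
    ydot[3] = q_per - q_ven + q_lad_out + q_lcx_out;

    if (ip[0] >= 20) {
        yout[0] = P_lv;   yout[1] = P_la;   yout[2] = P_art;  yout[3] = P_ven;
        yout[4] = q_ao;   yout[5] = q_mv;   yout[6] = q_per;  yout[7] = q_ven;
        yout[8] = q_lad_in;   yout[9] = q_lad_out;
        yout[10] = q_lcx_in;  yout[11] = q_lcx_out;
        yout[12] = imp_lad;   yout[13] = imp_lcx;
        yout[14] = cep;       yout[15] = ve_lad;  yout[16] = ve_lcx;
        yout[17] = sip;       yout[18] = e1;      yout[19] = e2;
    }
}
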