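/* Compiled right-hand side of the whole-body PBPK system.
 *
 * Mirrors the reference R implementation (rhs_whole_body) exactly; the R
 * version is retained as the readable specification and the two are
 * cross-checked in the test suite. Parameters are passed as a flat double
 * vector through set_pbpk_parms() before each integration segment (discrete
 * events restart the integrator, so the static buffer is safe in R's
 * single-threaded evaluator).
 *
 * State layout (0-based, ns GI segments, no organs):
 *   solid[ns] | diss[ns] | bile[ns-1] | prec[ns-1] | precb[ns-1] |
 *   cumabs[ns-1] | cumabs_bile | fecal | gb | gbe | tissue[no] |
 *   art | ven | metl | metg | el | eg | pg | pc
 *
 * Parameter layout: see pbpk_parms_vector() in R/pbpk_engine.R.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define MAX_PARMS 512
static double P[MAX_PARMS];
static int n_parms = 0;

void set_pbpk_parms(double *v, int *n)
{
    if (*n > MAX_PARMS)
        error("pbpk parameter vector too long (%d > %d)", *n, MAX_PARMS);
    for (int i = 0; i < *n; i++) P[i] = v[i];
    n_parms = *n;
}

void derivs_pbpk(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int ns = (int) P[0];
    const int no = (int) P[1];
    const int lung = (int) P[2] - 1;
    const int liver = (int) P[3] - 1;
    const int gut = (int) P[4] - 1;
    const int form_kind = (int) P[5];
    const double k_sol = P[6], k_prec = P[7];
    const double wt50 = P[8], wshape = P[9], flag = P[10], tdose = P[11];
    const double bp = P[12], fu = P[13], co = P[14], q_liv_tot = P[15];
    const double v_art = P[16], v_ven = P[17];
    const double kcat_cyp = P[18], km_cyp = P[19];
    const double cypL = P[20], cypG = P[21];
    const double kcat_mrp2 = P[22], km_mrp2 = P[23], mrp2 = P[24];
    const int ehc_on = (int) P[25];
    const double bile_reabs = P[26];
    const int gb_filling = (int) P[27];
    const double cont_frac = P[28], k_empty = P[29];
    const int has_perp = (int) P[30];
    const double pka = P[31], pcl = P[32], pv = P[33], pfu = P[34];
    const double pemax = P[35], pec50 = P[36], pkdl = P[37], pkdg = P[38];

    const double *gi_vol = P + 39;
    const double *sol_eff = gi_vol + ns;
    const double *kabs = sol_eff + ns;
    const double *ktr = kabs + ns;
    const double *org_vol = ktr + ns;
    const double *org_q = org_vol + no;
    const double *drains = org_q + no;     /* 0 venous, 1 portal, 2 lung */
    const double *kp = drains + no;

    /* state offsets */
    const int o_solid = 0;
    const int o_diss = ns;
    const int o_bile = 2 * ns;             /* ns-1 entries, segs 1..ns-1 */
    const int o_prec = 3 * ns - 1;
    const int o_precb = 4 * ns - 2;
    const int o_cumabs = 5 * ns - 3;
    const int o_cab_bile = 6 * ns - 4;
    const int o_fecal = 6 * ns - 3;
    const int o_gb = 6 * ns - 2;
    const int o_gbe = 6 * ns - 1;
    const int o_tis = 6 * ns;
    const int o_art = o_tis + no;
    const int o_ven = o_art + 1;
    const int o_metl = o_ven + 1;
    const int o_metg = o_metl + 1;
    const int o_el = o_metg + 1;
    const int o_eg = o_el + 1;
    const int o_pg = o_eg + 1;
    const int o_pc = o_pg + 1;

    const int n = o_pc + 1;
    for (int i = 0; i < n; i++) ydot[i] = 0.0;

    /* dissolution hazard, capped at k_sol */
    double hz;
    if (form_kind == 1) {
        hz = k_sol;
    } else if (form_kind == 2) {
        double tm = (*t - tdose) * 60.0 - flag;
        if (tm <= 0.0) {
            hz = 0.0;
        } else {
            hz = M_LN2 * wshape / wt50 * pow(tm / wt50, wshape - 1.0) * 60.0;
            if (hz > k_sol) hz = k_sol;
        }
    } else {
        hz = 0.0;
    }

    double sum_jd = 0.0, sum_jb = 0.0;
    double fecal_in = 0.0;

    for (int i = 0; i < ns; i++) {
        double s = y[o_solid + i];
        double d = y[o_diss + i];
        double b = (i == 0) ? 0.0 : y[o_bile + i - 1];
        double pr = (i == 0) ? 0.0 : y[o_prec + i - 1];
        double pb = (i == 0) ? 0.0 : y[o_precb + i - 1];

        double dtot = d + b;
        double sat = sol_eff[i] * gi_vol[i];
        double clamp = 1.0 - dtot / sat;
        if (clamp < 0.0) clamp = 0.0;
        double diss = hz * s * clamp;

        double excess = dtot - sat;
        if (excess < 0.0 || i == 0) excess = 0.0;
        double share_d = (dtot > 0.0) ? d / dtot : 0.0;
        double prec_d = k_prec * excess * share_d;
        double prec_b = k_prec * excess - prec_d;
        double rediss_d = k_prec * pr * clamp;
        double rediss_b = k_prec * pb * clamp;

        double out_s = ktr[i] * s;
        double out_d = ktr[i] * d;
        double out_b = ktr[i] * b;
        double out_p = ktr[i] * pr;
        double out_pb = ktr[i] * pb;

        double j_d = kabs[i] * d;
        double j_b = kabs[i] * b;
        sum_jd += j_d;
        sum_jb += j_b;

        ydot[o_solid + i] += -diss - out_s;
        ydot[o_diss + i] += diss - out_d - j_d - prec_d + rediss_d;
        if (i > 0) {
            ydot[o_bile + i - 1] += -out_b - j_b - prec_b + rediss_b;
            ydot[o_prec + i - 1] += prec_d - rediss_d - out_p;
            ydot[o_precb + i - 1] += prec_b - rediss_b - out_pb;
            ydot[o_cumabs + i - 1] = j_d;
        }

        if (i < ns - 1) {   /* transit into the next segment */
            ydot[o_solid + i + 1] += out_s;
            ydot[o_diss + i + 1] += out_d;
            ydot[o_bile + i] += out_b;
            ydot[o_prec + i] += out_p;
            ydot[o_precb + i] += out_pb;
        } else {            /* terminal segment -> faeces */
            fecal_in += out_s + out_d + out_b + out_p + out_pb;
        }
    }
    ydot[o_cab_bile] = sum_jb;

    /* blood and organs */
    double c_art = y[o_art] / v_art;
    double c_ven = y[o_ven] / v_ven;

    double ven_in = 0.0, portal_in = 0.0;
    double c_out_lung = 0.0, c_out_liver = 0.0;
    for (int i = 0; i < no; i++) {
        double c_out = y[o_tis + i] / org_vol[i] * bp / kp[i];
        if (i == lung) {
            ydot[o_tis + i] = co * (c_ven - c_out);
            c_out_lung = c_out;
        } else {
            ydot[o_tis + i] = org_q[i] * (c_art - c_out);
            if (i == liver) {
                c_out_liver = c_out;
            } else if ((int) drains[i] == 1) {
                portal_in += org_q[i] * c_out;
            } else {
                ven_in += org_q[i] * c_out;
            }
        }
    }

    double cu_liver = fu * (y[o_tis + liver] / org_vol[liver]) / kp[liver];
    double cu_gut = fu * (y[o_tis + gut] / org_vol[gut]) / kp[gut];
    double e_liver = y[o_el];
    double e_gut = y[o_eg];

    double met_liver = kcat_cyp * e_liver * cypL * cu_liver /
        (km_cyp + cu_liver);
    double met_gut = kcat_cyp * e_gut * cypG * cu_gut / (km_cyp + cu_gut);
    double bile_eff = kcat_mrp2 * mrp2 * cu_liver / (km_mrp2 + cu_liver);

    ydot[o_tis + gut] += sum_jd + sum_jb - met_gut;
    ydot[o_tis + liver] = org_q[liver] * c_art + portal_in -
        q_liv_tot * c_out_liver - met_liver - bile_eff;

    /* bile routing / gallbladder */
    double to_duo = 0.0;
    double fecal_extra = 0.0;
    if (bile_eff > 0.0 || y[o_gbe] > 0.0) {
        if (!ehc_on) {
            fecal_extra += bile_eff;
        } else {
            double keep = bile_reabs * bile_eff;
            fecal_extra += bile_eff - keep;
            if (gb_filling) {
                to_duo = keep * cont_frac;
                ydot[o_gb] = keep * (1.0 - cont_frac);
            } else {
                double eject = k_empty * y[o_gbe];
                to_duo = keep + eject;
                ydot[o_gb] = -eject;
                ydot[o_gbe] = -eject;
            }
        }
    }
    if (to_duo > 0.0) ydot[o_bile] += to_duo;   /* duodenum bile state */

    ydot[o_fecal] = fecal_in + fecal_extra;
    ydot[o_metl] = met_liver;
    ydot[o_metg] = met_gut;

    ydot[o_art] = co * c_out_lung - co * c_art;
    ydot[o_ven] = ven_in + q_liv_tot * c_out_liver - co * c_ven;

    /* perpetrator PK and CYP3A4 turnover */
    if (has_perp) {
        double ag = y[o_pg];
        double ac = y[o_pc];
        ydot[o_pg] = -pka * ag;
        ydot[o_pc] = pka * ag - pcl / pv * ac;
        double cu_perp = pfu * ac / pv;
        double fold = 1.0 + pemax * cu_perp / (pec50 + cu_perp);
        ydot[o_el] = pkdl * (fold - e_liver);
        ydot[o_eg] = pkdg * (fold - e_gut);
    }
}
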