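// Simulation engine: multi-layer soil water balance, root uptake resistance
// network, optimal big-leaf gas exchange and day-by-day vegetation dynamics.
// All internal units SI (m, s, mol) unless noted; interfaces use mm/h where
// the R level does.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

const double MOL_TO_MS = 1.8e-5;  // m s-1 water flux per (mol H2O m-2 s-1)
const double MS_TO_MMH = 3.6e6;   // mm h-1 per (m s-1)
const double LAMBDA_E  = 2.45e9;  // volumetric latent heat of vaporization, J m-3

struct SoilPar { double thr, ths, alpha, n, m, Ksat; };

SoilPar as_soil(const NumericVector& s) {
  SoilPar p;
  p.thr = s[0]; p.ths = s[1]; p.alpha = s[2]; p.n = s[3];
  p.m = 1.0 - 1.0 / s[3]; p.Ksat = s[4];
  return p;
}

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

inline double se_from_theta(double th, const SoilPar& s) {
  return clampd((th - s.thr) / (s.ths - s.thr), 1e-9, 1.0);
}

// van Genuchten retention, inverted: suction head (m) from effective saturation
inline double h_from_se(double se, const SoilPar& s) {
  if (se >= 1.0) return 0.0;
  double x = std::pow(se, -1.0 / s.m) - 1.0;
  double h = std::pow(x, 1.0 / s.n) / s.alpha;
  return std::min(h, 1e4);
}

// Mualem conductivity
inline double K_from_se(double se, const SoilPar& s) {
  if (se <= 0.0) return 0.0;
  double t = 1.0 - std::pow(1.0 - std::pow(se, 1.0 / s.m), s.m);
  return s.Ksat * std::sqrt(se) * t * t;
}

// ---------------------------------------------------------------------------
// Root water uptake: piecewise-linear resistor network.  psi total head (m),
// cond layer conductance (m s-1 per m head), demand m s-1.  Solves for the
// root-collar potential; no reverse flow (uptake >= 0 per layer).
double uptake_alloc(const std::vector<double>& psi, const std::vector<double>& cond,
                    double demand, double psi_min,
                    std::vector<double>& upt, bool& limited, double& psi_r) {
  int n = (int)psi.size();
  upt.assign(n, 0.0);
  limited = false; psi_r = psi_min;
  if (demand <= 0.0) return 0.0;
  double smax = 0.0;
  for (int i = 0; i < n; i++)
    if (cond[i] > 0.0) smax += cond[i] * std::max(0.0, psi[i] - psi_min);
  if (smax <= demand) {
    for (int i = 0; i < n; i++)
      if (cond[i] > 0.0) upt[i] = cond[i] * std::max(0.0, psi[i] - psi_min);
    limited = (smax < demand * (1.0 - 1e-12));
    return smax;
  }
  std::vector<int> idx;
  for (int i = 0; i < n; i++)
    if (cond[i] > 0.0 && psi[i] > psi_min) idx.push_back(i);
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return psi[a] > psi[b]; });
  double csum = 0.0, cpsi = 0.0;
  for (size_t j = 0; j < idx.size(); ++j) {
    csum += cond[idx[j]]; cpsi += cond[idx[j]] * psi[idx[j]];
    double next_psi = (j + 1 < idx.size()) ? psi[idx[j + 1]] : psi_min;
    double cand = (cpsi - demand) / csum;
    if (cand >= next_psi - 1e-15) { psi_r = cand; break; }
  }
  for (int i = 0; i < n; i++)
    if (cond[i] > 0.0) upt[i] = cond[i] * std::max(0.0, psi[i] - psi_r);
  return demand;
}

// ---------------------------------------------------------------------------
// Cowan-Farquhar optimal stomatal conductance, electron-transport limited.
// Mole fractions in mol mol-1; a4 = J/4 in mol m-2 s-1; lambda in mol H2O
// per mol CO2.  dEt/dAg = lambda reduces to a quadratic in ci.
struct GsRes { double gs, ci, Ag, Et; bool limited; };

// ci for prescribed gs (no-flux root ci = gam when gs*a4 degenerate)
double ci_from_gs(double gs, double a4, double ca, double gam) {
  if (gs <= 0.0) return gam;
  if (a4 <= 0.0) return ca;
  double B2 = -(gs * ca - 2.0 * gam * gs - a4);
  double C2 = -(2.0 * gam * gs * ca + a4 * gam);
  double disc = B2 * B2 - 4.0 * gs * C2;
  double ci = (-B2 + std::sqrt(std::max(disc, 0.0))) / (2.0 * gs);
  return clampd(ci, gam, ca);
}

GsRes gs_solve(double a4, double Dv, double ca, double gam, double lambda,
               double cap_Et, double gmax) {
  GsRes r; r.gs = 0.0; r.ci = gam; r.Ag = 0.0; r.Et = 0.0; r.limited = false;
  if (a4 <= 0.0 || ca <= gam || lambda <= 0.0 || cap_Et <= 0.0) {
    if (cap_Et <= 0.0 && a4 > 0.0 && ca > gam) r.limited = true;
    return r;
  }
  double gs;
  if (Dv <= 0.0) {
    gs = gmax;  // water costs nothing; supply cap cannot bind on Et = 0
  } else {
    double lmin = 1.6 * Dv / (ca - gam);
    if (lambda <= lmin * (1.0 + 1e-12)) return r;
    double k = 3.0 * gam * lambda / (1.6 * Dv);
    double A = 1.0 - k;
    double B = 2.0 * (k * ca - gam);
    double C = 3.0 * gam * ca - 2.0 * gam * gam - k * ca * ca;
    double ci_opt = -1.0;
    if (std::fabs(A) < 1e-14) {
      ci_opt = -C / B;
    } else {
      double disc = B * B - 4.0 * A * C;
      if (disc < 0.0) return r;
      double sq = std::sqrt(disc);
      double r1 = (-B + sq) / (2.0 * A), r2 = (-B - sq) / (2.0 * A);
      // unique admissible root in (gam, ca)
      bool ok1 = (r1 > gam && r1 < ca), ok2 = (r2 > gam && r2 < ca);
      if (ok1 && ok2) ci_opt = std::max(r1, r2);
      else if (ok1) ci_opt = r1;
      else if (ok2) ci_opt = r2;
      else return r;
    }
    if (!(ci_opt > gam && ci_opt < ca)) return r;
    gs = a4 * (ci_opt - gam) / ((ci_opt + 2.0 * gam) * (ca - ci_opt));
  }
  if (gs > gmax) gs = gmax;
  if (Dv > 0.0) {
    double gs_cap = cap_Et / (1.6 * Dv);
    if (gs > gs_cap) { gs = gs_cap; r.limited = true; }
  }
  if (gs <= 0.0) { r.gs = 0.0; return r; }
  double ci = ci_from_gs(gs, a4, ca, gam);
  r.gs = gs; r.ci = ci;
  r.Ag = gs * (ca - ci);
  r.Et = 1.6 * gs * Dv;
  return r;
}

// ---------------------------------------------------------------------------
// Soil water step with adaptive explicit sub-stepping.
struct SoilStepOut {
  double infil, runoff, drain, es, shortfall; // metres over the step
  int nsub;
  std::vector<double> uptP, uptS;             // metres extracted per layer
};

void soil_step(std::vector<double>& th, const SoilPar& sp,
               double Z, double zr, double sing, double dz, double Lc,
               double cdr, double rain_ms,
               const std::vector<double>& uptP_ms,
               const std::vector<double>& uptS_ms,
               double es_ms, double dt_total, double dtheta_max,
               int substep_max, SoilStepOut& out) {
  int n = (int)th.size();
  out.infil = out.runoff = out.drain = out.es = out.shortfall = 0.0;
  out.nsub = 0;
  out.uptP.assign(n, 0.0); out.uptS.assign(n, 0.0);
  std::vector<double> se(n), h(n), K(n), H(n), dth(n), outflow(n), scale(n);
  std::vector<double> q(std::max(0, n - 1));
  double t = 0.0;
  while (t < dt_total - 1e-9 && out.nsub < substep_max) {
    for (int i = 0; i < n; i++) {
      se[i] = se_from_theta(th[i], sp);
      h[i] = h_from_se(se[i], sp);
      K[i] = K_from_se(se[i], sp);
      H[i] = (Z - (i + 0.5) * dz) - h[i];
    }
    int nsat = 0;
    for (int i = n - 1; i >= 0; i--) { if (se[i] >= 0.9999) nsat++; else break; }
    double zw = nsat * dz;
    double qd = (zw > zr) ? cdr * sp.Ksat * sing * (zw - zr) / Lc : 0.0;
    int idrain = n - nsat;
    for (int i = 0; i < n - 1; i++) {
      double Keff = 0.5 * (K[i] + K[i + 1]);
      q[i] = Keff * (H[i] - H[i + 1]) / dz;
    }
    double f = std::min(rain_ms, sp.Ksat);
    for (int i = 0; i < n; i++) {
      double in = 0.0, outf = 0.0;
      if (i == 0) in += f;
      else { if (q[i - 1] > 0) in += q[i - 1]; else outf += -q[i - 1]; }
      if (i < n - 1) { if (q[i] > 0) outf += q[i]; else in += -q[i]; }
      outf += uptP_ms[i] + uptS_ms[i];
      if (i == 0) outf += es_ms;
      if (nsat > 0 && i == idrain) outf += qd;
      outflow[i] = outf;
      dth[i] = (in - outf) / dz;
    }
    double dmax = 1e-12;
    for (int i = 0; i < n; i++) dmax = std::max(dmax, std::fabs(dth[i]));
    double dt_s = std::min(dt_total - t, dtheta_max * (sp.ths - sp.thr) / dmax);
    dt_s = clampd(dt_s, 1e-3, dt_total - t);
    // donor-side scaling keeps every layer above residual content
    for (int i = 0; i < n; i++) {
      double avail = std::max(0.0, th[i] - sp.thr) * dz;
      scale[i] = (outflow[i] * dt_s > 0.95 * avail)
                   ? 0.95 * avail / (outflow[i] * dt_s + 1e-300) : 1.0;
      scale[i] = clampd(scale[i], 0.0, 1.0);
    }
    for (int i = 0; i < n - 1; i++)
      q[i] = (q[i] > 0) ? q[i] * scale[i] : q[i] * scale[i + 1];
    double es_a = es_ms * scale[0];
    double qd_a = (nsat > 0) ? qd * scale[idrain] : 0.0;
    for (int i = 0; i < n; i++) {
      double in = 0.0, outf = 0.0;
      if (i == 0) in += f;
      else { if (q[i - 1] > 0) in += q[i - 1]; else outf += -q[i - 1]; }
      if (i < n - 1) { if (q[i] > 0) outf += q[i]; else in += -q[i]; }
      double upP = uptP_ms[i] * scale[i], upS = uptS_ms[i] * scale[i];
      outf += upP + upS;
      if (i == 0) outf += es_a;
      if (nsat > 0 && i == idrain) outf += qd_a;
      th[i] += dt_s * (in - outf) / dz;
      out.uptP[i] += upP * dt_s; out.uptS[i] += upS * dt_s;
    }
    out.infil += f * dt_s;
    out.es += es_a * dt_s;
    out.drain += qd_a * dt_s;
    out.runoff += (rain_ms - f) * dt_s;
    for (int i = n - 1; i >= 1; i--)
      if (th[i] > sp.ths) { th[i - 1] += th[i] - sp.ths; th[i] = sp.ths; }
    if (th[0] > sp.ths) { out.runoff += (th[0] - sp.ths) * dz; th[0] = sp.ths; }
    for (int i = 0; i < n; i++)
      if (th[i] < sp.thr) { out.shortfall += (sp.thr - th[i]) * dz; th[i] = sp.thr; }
    t += dt_s;
    out.nsub++;
  }
}

double jmax_temp(double J25, double Ta, double Topt, double sigT) {
  double d = (Ta - Topt) * (Ta - Topt) - (25.0 - Topt) * (25.0 - Topt);
  return J25 * std::exp(-d / (2.0 * sigT * sigT));
}

struct DayState {
  double Jp, Js, MAs;
  std::vector<double> SArp, SArs;
};

}  // namespace

// ---------------------------------------------------------------------------
// Exported: one soil water balance step (used by step_soil_water()).
// [[Rcpp::export]]
List soil_step_cpp(NumericVector theta, NumericVector soil, NumericVector geom,
                   double rain_mm_h, NumericVector upt_p_mm_h,
                   NumericVector upt_s_mm_h, double es_mm_h, double dt_h,
                   double c_drain, double dtheta_max, int substep_max) {
  SoilPar sp = as_soil(soil);
  double Z = geom[0], zr = geom[1], g0 = geom[2], dz = geom[3], Lc = geom[4];
  int n = theta.size();
  std::vector<double> th(theta.begin(), theta.end());
  std::vector<double> upP(n), upS(n);
  for (int i = 0; i < n; i++) {
    upP[i] = upt_p_mm_h[i] / MS_TO_MMH;
    upS[i] = upt_s_mm_h[i] / MS_TO_MMH;
  }
  SoilStepOut out;
  soil_step(th, sp, Z, zr, std::sin(g0 * M_PI / 180.0), dz, Lc, c_drain,
            rain_mm_h / MS_TO_MMH, upP, upS, es_mm_h / MS_TO_MMH,
            dt_h * 3600.0, dtheta_max, substep_max, out);
  NumericVector th_out(th.begin(), th.end());
  NumericVector uP(out.uptP.begin(), out.uptP.end());
  NumericVector uS(out.uptS.begin(), out.uptS.end());
  return List::create(
    _["theta"] = th_out,
    _["infiltration_mm"] = out.infil * 1000.0,
    _["runoff_mm"] = out.runoff * 1000.0,
    _["drainage_mm"] = out.drain * 1000.0,
    _["soil_evap_mm"] = out.es * 1000.0,
    _["uptake_p_mm"] = uP * 1000.0,
    _["uptake_s_mm"] = uS * 1000.0,
    _["shortfall_mm"] = out.shortfall * 1000.0,
    _["substeps"] = out.nsub);
}

// ---------------------------------------------------------------------------
// Exported: full multi-year simulation.
// forc: matrix with columns ia (mol quanta m-2 s-1), ig (W m-2), ta (degC),
//       dv (mol mol-1), rain (mm h-1); one row per hour, days of 24 h.
// [[Rcpp::export]]
List simulate_vom_cpp(NumericMatrix forc, double ca_ppm, NumericVector soil,
                      NumericVector geom, NumericVector longterm,
                      NumericVector costs, List ctl, List init,
                      bool keep_logs) {
  SoilPar sp = as_soil(soil);
  double Z = geom[0], zr = geom[1], g0 = geom[2], dz = geom[3], Lc = geom[4];
  double sing = std::sin(g0 * M_PI / 180.0);
  int n = (int)std::lround(Z / dz);

  double MAp = longterm[0], yrp = longterm[1];
  double cfp = longterm[2], cep = longterm[3];
  double cfs = longterm[4], ces = longterm[5];
  int irp = std::min(n, std::max(1, (int)std::lround(yrp / dz)));
  int irs = std::min(n, std::max(1, (int)std::lround(1.0 / dz)));

  double cMf = costs[0], cJv = costs[1], cr = costs[2], cw = costs[3],
         cwd = costs[4], jexp = costs[5];
  auto jcost = [&](double J) { return cJv * std::pow(J, jexp); };

  double aq = as<double>(ctl["alpha_q"]);
  double gam_ppm = as<double>(ctl["gamma_star"]);
  double Topt = as<double>(ctl["t_opt"]);
  double sigT = as<double>(ctl["sigma_t"]);
  double gmax = as<double>(ctl["g_max"]);
  double psi_min = as<double>(ctl["psi_min"]);
  double c_soil = as<double>(ctl["c_soil"]);
  double r_root = as<double>(ctl["r_root"]);
  double c_es = as<double>(ctl["c_es"]);
  double cdr = as<double>(ctl["c_drain"]);
  double lam_max = as<double>(ctl["lambda_max"]);
  double step = as<double>(ctl["adjust_step"]);
  double probe = as<double>(ctl["probe_step"]);
  double j_floor = as<double>(ctl["j_floor"]);
  double j_cap = as<double>(ctl["j_cap"]);
  double ma_floor = as<double>(ctl["ma_floor"]);
  double sar_floor = as<double>(ctl["sar_floor"]);
  double sar_cap = as<double>(ctl["sar_cap"]);
  double dtheta_max = as<double>(ctl["dtheta_max"]);
  int substep_max = as<int>(ctl["substep_max"]);

  double ca = ca_ppm * 1e-6, gam = gam_ppm * 1e-6;

  NumericVector th0 = as<NumericVector>(init["theta"]);
  std::vector<double> th(th0.begin(), th0.end());
  DayState st;
  st.Jp = as<double>(init["jmax25_p"]);
  st.Js = as<double>(init["jmax25_s"]);
  st.MAs = std::min(as<double>(init["ma_s"]), std::max(0.0, 1.0 - MAp));
  double sar0 = as<double>(init["sar"]);
  st.SArp.assign(n, 0.0); st.SArs.assign(n, 0.0);
  for (int i = 0; i < irp; i++) st.SArp[i] = sar0;
  for (int i = 0; i < irs; i++) st.SArs[i] = sar0;

  int n_hours = forc.nrow();
  int n_days = n_hours / 24;

  // replay buffers for the marginal-NCP probes (previous day, frozen soil)
  std::vector<double> psi_b(24 * n), u_b(24 * n), ia_b(24), ta_b(24), dv_b(24);
  double lam_p = 0.0, lam_s = 0.0;

  // logs
  const int HC = 24;  // hourly log columns
  NumericMatrix hlog = keep_logs ? NumericMatrix(n_hours, HC) : NumericMatrix(1, 1);
  const int DC = 15;
  NumericMatrix dlog(n_days, DC);

  double storage0 = 0.0;
  for (int i = 0; i < n; i++) storage0 += th[i] * dz * 1000.0;

  double tot_P = 0, tot_infil = 0, tot_runoff = 0, tot_drain = 0, tot_es = 0,
         tot_etp = 0, tot_ets = 0, tot_short = 0;
  double A_day = 0.0, NCP = 0.0, A_total = 0.0;

  std::vector<double> se(n), h(n), K(n), u(n), psi(n), condP(n), condS(n);
  std::vector<double> uptP_req(n), uptS_req(n);
  std::vector<double> upl;

  // ground-area assimilation one component would have achieved over the
  // stored day (soil trajectory frozen) for candidate properties
  auto replay_comp = [&](int comp, double J25, double MA,
                         const std::vector<double>& SAr) -> double {
    double lam = comp == 0 ? lam_p : lam_s;
    int ir = comp == 0 ? irp : irs;
    if (MA <= 0.0) return 0.0;
    double A = 0.0;
    for (int hh = 0; hh < 24; hh++) {
      double ia_umol = ia_b[hh] * 1e6;
      if (ia_umol <= 0.0) continue;
      double JT = jmax_temp(J25, ta_b[hh], Topt, sigT);
      double J = aq * ia_umol * JT / (aq * ia_umol + JT);
      double a4 = J / 4.0 * 1e-6;
      double smax = 0.0;
      for (int i = 0; i < ir; i++)
        smax += SAr[i] * dz * u_b[hh * n + i] *
                std::max(0.0, psi_b[hh * n + i] - psi_min);
      double capE = smax / (MA * MOL_TO_MS);
      GsRes g = gs_solve(a4, dv_b[hh], ca, gam, lam, capE, gmax);
      A += g.Ag * MA * 3600.0;
    }
    return A;
  };

  double Rfol_cur = 0, Rroot_cur = 0, Rwood_cur = 0;
  auto current_costs = [&]() {
    Rfol_cur = cMf * (MAp + st.MAs) +
               jcost(st.Jp) * MAp + jcost(st.Js) * st.MAs;
    double rr = 0.0;
    for (int i = 0; i < n; i++) rr += (st.SArp[i] + st.SArs[i]) * dz;
    Rroot_cur = cr * rr;
    Rwood_cur = cw * MAp * (1.0 + cwd * yrp);
  };

  int day = -1;
  for (int hidx = 0; hidx < n_hours; hidx++) {
    int hod = hidx % 24;
    double ia = forc(hidx, 0), ig = forc(hidx, 1), ta = forc(hidx, 2),
           dv = forc(hidx, 3), rain = forc(hidx, 4);

    // layer properties for this hour
    for (int i = 0; i < n; i++) {
      se[i] = se_from_theta(th[i], sp);
      h[i] = h_from_se(se[i], sp);
      K[i] = K_from_se(se[i], sp);
      u[i] = 1.0 / (r_root + 1.0 / (c_soil * K[i] + 1e-300));
      // uptake network uses matric potential only; elevation differences
      // within the root zone are negligible against psi_min
      psi[i] = -h[i];
    }

    if (hod == 0) {
      // close previous day: accounting, then hill-climbing adjustment
      if (day >= 0) {
        current_costs();
        double ncp_day = A_day - Rfol_cur - Rroot_cur - Rwood_cur;
        NCP += ncp_day; A_total += A_day;
        double raip = 0, rais = 0;
        for (int i = 0; i < n; i++) { raip += st.SArp[i] * dz; rais += st.SArs[i] * dz; }
        dlog(day, 0) = day + 1;   dlog(day, 1) = st.Jp;  dlog(day, 2) = st.Js;
        dlog(day, 3) = MAp;       dlog(day, 4) = st.MAs; dlog(day, 5) = yrp;
        dlog(day, 6) = raip;      dlog(day, 7) = rais;   dlog(day, 8) = A_day;
        dlog(day, 9) = Rfol_cur;  dlog(day, 10) = Rroot_cur;
        dlog(day, 11) = Rwood_cur; dlog(day, 12) = ncp_day;
        dlog(day, 13) = lam_p;    dlog(day, 14) = lam_s;

        // day-by-day optimization on yesterday's frozen soil trajectory.
        // Photosynthetic capacity carries no structural inertia: each leaf
        // re-tunes J_max25 by a multiplicative ladder search (quasi-direct
        // daily optimization). Cover and roots are structures built from
        // carbon: they move by one bounded hill-climbing step per day.
        static const double ladder[7] = {1.0 / 3, 2.0 / 3, 0.9, 1.0,
                                         1.1, 1.5, 3.0};
        auto tune_j = [&](double Jcur, double MA,
                          const std::vector<double>& SAr, int comp) {
          double bestJ = Jcur, bestV = -1e300;
          for (int k = 0; k < 7; k++) {
            double Jc = clampd(Jcur * ladder[k], j_floor, j_cap);
            double v = replay_comp(comp, Jc, MA, SAr) - jcost(Jc) * MA;
            if (v > bestV) { bestV = v; bestJ = Jc; }
          }
          return bestJ;
        };
        st.Jp = tune_j(st.Jp, MAp, st.SArp, 0);
        st.Js = tune_j(st.Js, st.MAs, st.SArs, 1);

        auto bump = [&](double& x, double sens, double lo, double hi) {
          if (sens == 0.0) return;   // zero gain: exact fixed point
          x *= (sens > 0) ? (1.0 + step) : (1.0 - step);
          x = clampd(x, lo, hi);
        };
        // seasonal cover: marginal gain includes its foliage+capacity cost
        {
          double base_s = replay_comp(1, st.Js, st.MAs, st.SArs) -
            (cMf + jcost(st.Js)) * st.MAs;
          double MAc = std::min(st.MAs * (1.0 + probe),
                                std::max(0.0, 1.0 - MAp));
          double cand_s = replay_comp(1, st.Js, MAc, st.SArs) -
            (cMf + jcost(st.Js)) * MAc;
          bump(st.MAs, cand_s - base_s, ma_floor, std::max(0.0, 1.0 - MAp));
          if (1.0 - MAp < ma_floor) st.MAs = std::max(0.0, 1.0 - MAp);
        }
        // root surface areas, layer by layer, each component
        double base_p = replay_comp(0, st.Jp, MAp, st.SArp);
        double base_s2 = replay_comp(1, st.Js, st.MAs, st.SArs);
        std::vector<double> SAc;
        for (int i = 0; i < irp; i++) {
          SAc = st.SArp; SAc[i] = st.SArp[i] * (1.0 + probe);
          double gain = replay_comp(0, st.Jp, MAp, SAc) - base_p -
            cr * dz * (SAc[i] - st.SArp[i]);
          bump(st.SArp[i], gain, sar_floor, sar_cap);
        }
        for (int i = 0; i < irs; i++) {
          SAc = st.SArs; SAc[i] = st.SArs[i] * (1.0 + probe);
          double gain = replay_comp(1, st.Js, st.MAs, SAc) - base_s2 -
            cr * dz * (SAc[i] - st.SArs[i]);
          bump(st.SArs[i], gain, sar_floor, sar_cap);
        }
      }
      day++;
      A_day = 0.0;
      // daily water-use parameters from current (midnight) suction profile
      double shp = 0.0, shs = 0.0;
      for (int i = 0; i < irp; i++) shp += h[i];
      for (int i = 0; i < irs; i++) shs += h[i];
      lam_p = (shp > 0.0) ? cfp * std::pow(shp, cep) : lam_max;
      lam_s = (shs > 0.0) ? cfs * std::pow(shs, ces) : lam_max;
      lam_p = clampd(lam_p, 0.0, lam_max);
      lam_s = clampd(lam_s, 0.0, lam_max);
    }

    // stash replay buffers
    ia_b[hod] = ia; ta_b[hod] = ta; dv_b[hod] = dv;
    for (int i = 0; i < n; i++) {
      psi_b[hod * n + i] = psi[i];
      u_b[hod * n + i] = u[i];
    }

    // canopy gas exchange per big leaf
    GsRes gp, gs_;
    double supply_p = 0.0, supply_s = 0.0;
    for (int i = 0; i < n; i++) {
      condP[i] = (i < irp) ? st.SArp[i] * dz * u[i] : 0.0;
      condS[i] = (i < irs) ? st.SArs[i] * dz * u[i] : 0.0;
      supply_p += condP[i] * std::max(0.0, psi[i] - psi_min);
      supply_s += condS[i] * std::max(0.0, psi[i] - psi_min);
    }
    double ia_umol = ia * 1e6;
    {
      double JT = jmax_temp(st.Jp, ta, Topt, sigT);
      double J = (ia_umol > 0) ? aq * ia_umol * JT / (aq * ia_umol + JT) : 0.0;
      double capE = (MAp > 0) ? supply_p / (MAp * MOL_TO_MS) : 0.0;
      gp = gs_solve(J / 4.0 * 1e-6, dv, ca, gam, lam_p, capE, gmax);
    }
    {
      double JT = jmax_temp(st.Js, ta, Topt, sigT);
      double J = (ia_umol > 0) ? aq * ia_umol * JT / (aq * ia_umol + JT) : 0.0;
      double capE = (st.MAs > 0) ? supply_s / (st.MAs * MOL_TO_MS) : 0.0;
      gs_ = gs_solve(J / 4.0 * 1e-6, dv, ca, gam, lam_s, capE, gmax);
    }
    double demP = gp.Et * MAp * MOL_TO_MS;        // m s-1 ground
    double demS = gs_.Et * st.MAs * MOL_TO_MS;

    bool limP, limS; double prP, prS;
    uptake_alloc(psi, condP, demP, psi_min, uptP_req, limP, prP);
    std::vector<double> uptS_tmp;
    uptake_alloc(psi, condS, demS, psi_min, uptS_req, limS, prS);

    // soil evaporation (shading x surface moisture x radiative potential)
    double fpc = std::min(1.0, MAp + st.MAs);
    double es_ms = (1.0 - fpc) * se[0] * c_es * ig / LAMBDA_E;

    SoilStepOut sout;
    soil_step(th, sp, Z, zr, sing, dz, Lc, cdr, rain / MS_TO_MMH,
              uptP_req, uptS_req, es_ms, 3600.0, dtheta_max, substep_max, sout);

    double etp_mm = 0, ets_mm = 0;
    for (int i = 0; i < n; i++) { etp_mm += sout.uptP[i]; ets_mm += sout.uptS[i]; }
    etp_mm *= 1000.0; ets_mm *= 1000.0;

    A_day += (gp.Ag * MAp + gs_.Ag * st.MAs) * 3600.0;

    tot_P += rain; tot_infil += sout.infil * 1000.0;
    tot_runoff += sout.runoff * 1000.0; tot_drain += sout.drain * 1000.0;
    tot_es += sout.es * 1000.0; tot_etp += etp_mm; tot_ets += ets_mm;
    tot_short += sout.shortfall * 1000.0;

    if (keep_logs) {
      double stor = 0.0;
      for (int i = 0; i < n; i++) stor += th[i] * dz * 1000.0;
      double avth = 0.0;
      for (int i = 0; i < irp; i++) avth += se[i];
      avth /= irp;
      hlog(hidx, 0) = hidx + 1;   hlog(hidx, 1) = ia;     hlog(hidx, 2) = ta;
      hlog(hidx, 3) = dv;         hlog(hidx, 4) = rain;
      hlog(hidx, 5) = sout.infil * 1000.0;
      hlog(hidx, 6) = sout.runoff * 1000.0;
      hlog(hidx, 7) = sout.drain * 1000.0;
      hlog(hidx, 8) = sout.es * 1000.0;
      hlog(hidx, 9) = etp_mm;     hlog(hidx, 10) = ets_mm;
      hlog(hidx, 11) = gp.gs;     hlog(hidx, 12) = gs_.gs;
      hlog(hidx, 13) = gp.ci * 1e6; hlog(hidx, 14) = gs_.ci * 1e6;
      hlog(hidx, 15) = gp.Ag * 1e6; hlog(hidx, 16) = gs_.Ag * 1e6;
      hlog(hidx, 17) = lam_p;     hlog(hidx, 18) = lam_s;
      hlog(hidx, 19) = supply_p * MS_TO_MMH;
      hlog(hidx, 20) = supply_s * MS_TO_MMH;
      hlog(hidx, 21) = se[0];     hlog(hidx, 22) = avth;
      hlog(hidx, 23) = stor;
    }
  }
  // close final day
  if (day >= 0 && day < n_days) {
    current_costs();
    double ncp_day = A_day - Rfol_cur - Rroot_cur - Rwood_cur;
    NCP += ncp_day; A_total += A_day;
    double raip = 0, rais = 0;
    for (int i = 0; i < n; i++) { raip += st.SArp[i] * dz; rais += st.SArs[i] * dz; }
    dlog(day, 0) = day + 1;   dlog(day, 1) = st.Jp;  dlog(day, 2) = st.Js;
    dlog(day, 3) = MAp;       dlog(day, 4) = st.MAs; dlog(day, 5) = yrp;
    dlog(day, 6) = raip;      dlog(day, 7) = rais;   dlog(day, 8) = A_day;
    dlog(day, 9) = Rfol_cur;  dlog(day, 10) = Rroot_cur;
    dlog(day, 11) = Rwood_cur; dlog(day, 12) = ncp_day;
    dlog(day, 13) = lam_p;    dlog(day, 14) = lam_s;
  }

  double storage1 = 0.0;
  for (int i = 0; i < n; i++) storage1 += th[i] * dz * 1000.0;
  NumericVector th_out(th.begin(), th.end());

  List totals = List::create(
    _["P_mm"] = tot_P, _["infiltration_mm"] = tot_infil,
    _["runoff_mm"] = tot_runoff, _["drainage_mm"] = tot_drain,
    _["E_s_mm"] = tot_es, _["E_t_p_mm"] = tot_etp, _["E_t_s_mm"] = tot_ets,
    _["shortfall_mm"] = tot_short,
    _["dstorage_mm"] = storage1 - storage0,
    _["ncp_mol"] = NCP, _["assim_mol"] = A_total);

  return List::create(
    _["totals"] = totals,
    _["daily"] = dlog,
    _["hourly"] = hlog,
    _["theta_final"] = th_out,
    _["ncp"] = NCP);
}
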