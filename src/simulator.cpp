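// Reduced closed-loop 0D cardio-respiratory model, integrated with a
// fixed-step fourth-order Runge-Kutta scheme.
//
// State vector (15):
//   0..7  compartment volumes: la, lv, ra, rv, sa, sv, pa, pv   [mL]
//   8     u     fraction of the cardiac cycle in [0,1)
//   9     T     instantaneous heart period [s]
//   10    Pbar  low-pass filtered systemic arterial pressure [mmHg]
//   11    PAO2  alveolar O2 partial pressure [mmHg]
//   12    PACO2 alveolar CO2 partial pressure [mmHg]
//   13    CvO2  mixed-venous O2 content [mL/mL]
//   14    CvCO2 mixed-venous CO2 content [mL/mL]
//
// Saved signals (9): T, u, Psa, Ptv, qAV, VLV, SaO2, PaO2, PaCO2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Pars {
  double Vtot, Vu_ven, T0, GTv, Pn, Emax_LV0, kE_LV, kE_RV, FiO2, hgb,
      Csat_CO2, hO2, hCO2, kCO2;
  double Emax_RV0, k_sym, P0_LV, P0_RV, Vu_LV, Vu_RV;
  double C_sa, Vu_sa, C_sv, C_pa, Vu_pa, C_pv, Vu_pv, C_la, Vu_la, C_ra,
      Vu_ra;
  double R_sys, R_vr, R_pul, R_pvein, R_mv, R_av, R_tc, R_pvalve, R_rev;
  double Tsys0, ksys, f_min, f_max, ka, fev0, fev_inf, fcs0, kev, tau_T,
      tau_p, resp_T_mod;
  double VA_vol, Vdot_A0, G_vent, T_resp, vent_amp, sh, alpha_O2, Hufner,
      beta_O2, K_O2, beta_CO2, M_O2, M_CO2, Vtis_O2, Vtis_CO2, Patm, P_H2O;
};

double getp(const NumericVector& v, const char* nm) {
  if (!v.containsElementNamed(nm)) stop("missing parameter: %s", nm);
  return v[nm];
}

Pars load_pars(const NumericVector& p) {
  Pars q;
  q.Vtot = getp(p, "Vtot"); q.Vu_ven = getp(p, "Vu_ven");
  q.T0 = getp(p, "T0"); q.GTv = getp(p, "GTv"); q.Pn = getp(p, "Pn");
  q.Emax_LV0 = getp(p, "Emax_LV0"); q.kE_LV = getp(p, "kE_LV");
  q.kE_RV = getp(p, "kE_RV"); q.FiO2 = getp(p, "FiO2");
  q.hgb = getp(p, "hgb"); q.Csat_CO2 = getp(p, "Csat_CO2");
  q.hO2 = getp(p, "hO2"); q.hCO2 = getp(p, "hCO2"); q.kCO2 = getp(p, "kCO2");
  q.Emax_RV0 = getp(p, "Emax_RV0"); q.k_sym = getp(p, "k_sym");
  q.P0_LV = getp(p, "P0_LV"); q.P0_RV = getp(p, "P0_RV");
  q.Vu_LV = getp(p, "Vu_LV"); q.Vu_RV = getp(p, "Vu_RV");
  q.C_sa = getp(p, "C_sa"); q.Vu_sa = getp(p, "Vu_sa");
  q.C_sv = getp(p, "C_sv");
  q.C_pa = getp(p, "C_pa"); q.Vu_pa = getp(p, "Vu_pa");
  q.C_pv = getp(p, "C_pv"); q.Vu_pv = getp(p, "Vu_pv");
  q.C_la = getp(p, "C_la"); q.Vu_la = getp(p, "Vu_la");
  q.C_ra = getp(p, "C_ra"); q.Vu_ra = getp(p, "Vu_ra");
  q.R_sys = getp(p, "R_sys"); q.R_vr = getp(p, "R_vr");
  q.R_pul = getp(p, "R_pul"); q.R_pvein = getp(p, "R_pvein");
  q.R_mv = getp(p, "R_mv"); q.R_av = getp(p, "R_av");
  q.R_tc = getp(p, "R_tc"); q.R_pvalve = getp(p, "R_pvalve");
  q.R_rev = getp(p, "R_rev");
  q.Tsys0 = getp(p, "Tsys0"); q.ksys = getp(p, "ksys");
  q.f_min = getp(p, "f_min"); q.f_max = getp(p, "f_max");
  q.ka = getp(p, "ka"); q.fev0 = getp(p, "fev0");
  q.fev_inf = getp(p, "fev_inf"); q.fcs0 = getp(p, "fcs0");
  q.kev = getp(p, "kev"); q.tau_T = getp(p, "tau_T");
  q.tau_p = getp(p, "tau_p"); q.resp_T_mod = getp(p, "resp_T_mod");
  q.VA_vol = getp(p, "VA_vol"); q.Vdot_A0 = getp(p, "Vdot_A0");
  q.G_vent = getp(p, "G_vent"); q.T_resp = getp(p, "T_resp");
  q.vent_amp = getp(p, "vent_amp"); q.sh = getp(p, "sh");
  q.alpha_O2 = getp(p, "alpha_O2"); q.Hufner = getp(p, "Hufner");
  q.beta_O2 = getp(p, "beta_O2"); q.K_O2 = getp(p, "K_O2");
  q.beta_CO2 = getp(p, "beta_CO2"); q.M_O2 = getp(p, "M_O2");
  q.M_CO2 = getp(p, "M_CO2"); q.Vtis_O2 = getp(p, "Vtis_O2");
  q.Vtis_CO2 = getp(p, "Vtis_CO2"); q.Patm = getp(p, "Patm");
  q.P_H2O = getp(p, "P_H2O");
  return q;
}

inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// O2 saturation (fraction) from partial pressure, Spencer-type curve
inline double sat_o2(double P, const Pars& p) {
  if (P <= 0) return 0.0;
  double X = P * (1.0 + p.beta_O2 * P);
  double Xh = std::pow(X, 1.0 / p.hO2);
  return Xh / (p.K_O2 + Xh);
}

// inverse of sat_o2
inline double sat_o2_inv(double S, const Pars& p) {
  S = clampd(S, 1e-9, 1.0 - 1e-9);
  double Xh = p.K_O2 * S / (1.0 - S);
  double X = std::pow(Xh, p.hO2);
  return (-1.0 + std::sqrt(1.0 + 4.0 * p.beta_O2 * X)) / (2.0 * p.beta_O2);
}

// fractional CO2 saturation from partial pressure
inline double frac_co2(double P, const Pars& p) {
  if (P <= 0) return 0.0;
  double X = P * (1.0 + p.beta_CO2 * P);
  double Xh = std::pow(X, 1.0 / p.hCO2);
  return Xh / (p.kCO2 + Xh);
}

inline double frac_co2_inv(double F, const Pars& p) {
  F = clampd(F, 1e-9, 1.0 - 1e-9);
  double Xh = p.kCO2 * F / (1.0 - F);
  double X = std::pow(Xh, p.hCO2);
  return (-1.0 + std::sqrt(1.0 + 4.0 * p.beta_CO2 * X)) / (2.0 * p.beta_CO2);
}

inline double valve_flow(double dp, double Rfwd, double Rrev) {
  return dp > 0 ? dp / Rfwd : dp / Rrev;
}

// right-hand side; fills dydt and the 9 output signals
void deriv(double t, const double* y, double* dydt, double* out,
           const Pars& p) {
  const double Vla = y[0], Vlv = y[1], Vra = y[2], Vrv = y[3], Vsa = y[4],
               Vsv = y[5], Vpa = y[6], Vpv = y[7], u = y[8], T = y[9],
               Pbar = y[10], PAO2 = y[11], PACO2 = y[12], CvO2 = y[13],
               CvCO2 = y[14];

  // ventricular activation
  double Tsys = p.Tsys0 - p.ksys / T;
  double usys = clampd(Tsys / T, 0.2, 0.6);
  double uu = u - std::floor(u);
  double phi = 0.0;
  if (uu < usys) {
    double s = std::sin(M_PI * uu / usys);
    phi = s * s;
  }
  double Emlv = p.k_sym * p.Emax_LV0;
  double Emrv = p.k_sym * p.Emax_RV0;
  double Plv = phi * Emlv * (Vlv - p.Vu_LV) +
               (1.0 - phi) * p.P0_LV * (std::exp(p.kE_LV * Vlv) - 1.0);
  double Prv = phi * Emrv * (Vrv - p.Vu_RV) +
               (1.0 - phi) * p.P0_RV * (std::exp(p.kE_RV * Vrv) - 1.0);
  double Pla = (Vla - p.Vu_la) / p.C_la;
  double Pra = (Vra - p.Vu_ra) / p.C_ra;
  double Psa = (Vsa - p.Vu_sa) / p.C_sa;
  double Psv = (Vsv - p.Vu_ven) / p.C_sv;
  double Ppa = (Vpa - p.Vu_pa) / p.C_pa;
  double Ppv = (Vpv - p.Vu_pv) / p.C_pv;

  double qmv = valve_flow(Pla - Plv, p.R_mv, p.R_rev);
  double qav = valve_flow(Plv - Psa, p.R_av, p.R_rev);
  double qtc = valve_flow(Pra - Prv, p.R_tc, p.R_rev);
  double qpval = valve_flow(Prv - Ppa, p.R_pvalve, p.R_rev);
  double qsys = (Psa - Psv) / p.R_sys;
  double qvr = (Psv - Pra) / p.R_vr;
  double qpul = (Ppa - Ppv) / p.R_pul;
  double qpvein = (Ppv - Pla) / p.R_pvein;

  dydt[0] = qpvein - qmv;
  dydt[1] = qmv - qav;
  dydt[2] = qvr - qtc;
  dydt[3] = qtc - qpval;
  dydt[4] = qav - qsys;
  dydt[5] = qsys - qvr;
  dydt[6] = qpval - qpul;
  dydt[7] = qpul - qpvein;

  // vagal baroreflex on heart period
  double e1 = std::exp((Pbar - p.Pn) / p.ka);
  double fcs = (p.f_min + p.f_max * e1) / (1.0 + e1);
  double e2 = std::exp((fcs - p.fcs0) / p.kev);
  double fev = p.fev0 + (p.fev_inf - p.fev0) * e2 / (1.0 + e2);
  double Ttar = p.T0 + p.GTv * fev +
                p.resp_T_mod * std::sin(2.0 * M_PI * t / p.T_resp);
  dydt[8] = 1.0 / T;
  dydt[9] = (Ttar - T) / p.tau_T;
  dydt[10] = (Psa - Pbar) / p.tau_p;

  // gas exchange
  double cap = p.Hufner * p.hgb;
  double S_ec = sat_o2(PAO2, p);
  double S_v = clampd(CvO2 / cap, 0.0, 1.0 - 1e-9);
  double S_a = clampd((1.0 - p.sh) * S_ec + p.sh * S_v, 1e-9, 1.0 - 1e-9);
  double PaO2a = sat_o2_inv(S_a, p);
  double CaO2 = cap * S_a + p.alpha_O2 * PaO2a;
  double CecO2 = cap * S_ec + p.alpha_O2 * PAO2;
  double CecCO2 = p.Csat_CO2 * frac_co2(PACO2, p);
  double CaCO2 = (1.0 - p.sh) * CecCO2 + p.sh * CvCO2;
  double PaCO2a = frac_co2_inv(CaCO2 / p.Csat_CO2, p);

  double vent_ctrl =
      clampd(1.0 + p.G_vent * (PaCO2a - 40.0), 0.3, 3.0) * p.Vdot_A0;
  double breath = 1.0 + p.vent_amp * std::sin(2.0 * M_PI * t / p.T_resp);
  double VdotA = vent_ctrl * (breath > 0 ? breath : 0.0);
  double PIO2 = (p.FiO2 / 100.0) * (p.Patm - p.P_H2O);
  double qp = qpul > 0 ? qpul : 0.0;
  double qs = qsys > 0 ? qsys : 0.0;

  dydt[11] = (VdotA * (PIO2 - PAO2) - 863.0 * qp * (CecO2 - CvO2)) / p.VA_vol;
  dydt[12] = (-VdotA * PACO2 + 863.0 * qp * (CvCO2 - CecCO2)) / p.VA_vol;
  dydt[13] = (qs * (CaO2 - CvO2) - p.M_O2) / p.Vtis_O2;
  dydt[14] = (qs * (CaCO2 - CvCO2) + p.M_CO2) / p.Vtis_CO2;

  if (out != nullptr) {
    out[0] = T;
    out[1] = uu;
    out[2] = Psa;
    out[3] = Psv;    // thoracic/central vein pressure
    out[4] = qav;
    out[5] = Vlv;
    out[6] = 100.0 * S_a;
    out[7] = PaO2a;
    out[8] = PaCO2a;
  }
}

}  // namespace

// [[Rcpp::export(name = ".cr_integrate")]]
List cr_integrate(NumericVector params, NumericVector y0, double dt,
                  double t_end, NumericMatrix windows, double sampling) {
  Pars p = load_pars(params);
  const int ns = 15;
  if (y0.size() != ns) stop("y0 must have length 15");
  double y[ns], k1[ns], k2[ns], k3[ns], k4[ns], yt[ns];
  for (int i = 0; i < ns; ++i) y[i] = y0[i];

  long nsteps = (long)std::llround(t_end / dt);
  long every = (long)std::llround(sampling / dt);
  if (every < 1) stop("sampling period must be >= dt");

  int nw = windows.nrow();
  std::vector<double> tv;
  std::vector<int> wv;
  std::vector<double> sig[9];

  double out[9];
  const double eps = 1e-9;

  // sample at t = 0 if inside a window
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % every == 0) {
      for (int w = 0; w < nw; ++w) {
        if (t >= windows(w, 0) - eps && t <= windows(w, 1) + eps) {
          deriv(t, y, k1, out, p);
          tv.push_back(t);
          wv.push_back(w + 1);
          for (int s = 0; s < 9; ++s) sig[s].push_back(out[s]);
          break;
        }
      }
    }
    if (step == nsteps) break;

    // classic RK4 step
    deriv(t, y, k1, nullptr, p);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    deriv(t + 0.5 * dt, yt, k2, nullptr, p);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    deriv(t + 0.5 * dt, yt, k3, nullptr, p);
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + dt * k3[i];
    deriv(t + dt, yt, k4, nullptr, p);
    for (int i = 0; i < ns; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    // cardiac cycle phase reset
    if (y[8] >= 1.0) y[8] -= std::floor(y[8]);

    if (step % 200 == 0) {
      bool bad = false;
      for (int i = 0; i < ns; ++i)
        if (!std::isfinite(y[i])) bad = true;
      if (bad) {
        return List::create(_["ok"] = false, _["t_fail"] = t + dt,
                            _["time"] = NumericVector(0));
      }
    }
  }
  for (int i = 0; i < ns; ++i)
    if (!std::isfinite(y[i]))
      return List::create(_["ok"] = false, _["t_fail"] = t_end,
                          _["time"] = NumericVector(0));

  int n = tv.size();
  NumericMatrix signals(n, 9);
  for (int s = 0; s < 9; ++s)
    for (int i = 0; i < n; ++i) signals(i, s) = sig[s][i];
  colnames(signals) =
      CharacterVector::create("T", "u", "Psa", "Ptv", "qAV", "VLV", "SaO2",
                              "PaO2", "PaCO2");
  return List::create(_["ok"] = true, _["t_fail"] = NA_REAL,
                      _["time"] = wrap(tv), _["window"] = wrap(wv),
                      _["signals"] = signals);
}
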