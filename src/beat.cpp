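// Closed-loop 0D circulation core.
//
// Eight volume states: LA, LV, RA, RV, systemic arteries (AO), systemic
// veins (SV), pulmonary arteries (PA), pulmonary veins (PU).  Chambers are
// time-varying elastance elements (raised-cosine activation, exponential
// relaxation with time constant tau, exponential passive EDPVR); valves are
// Bernoulli orifices with a small linear series resistance (characteristic
// impedance) -- inertial for the AV valves, quasi-steady for the semilunar
// valves; beds are RC windkessels.  Fixed-step RK4 on a sub-millisecond
// grid; outputs are sampled every 1 ms.
//
// Units at this interface: mmHg, mL, mL/s, cm^2, s.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double RHO_BLOOD = 1050.0;   // kg/m^3
static const double PA_PER_MMHG = 133.322;

struct Chamber {
  double emax;   // active elastance amplitude (mmHg/mL)
  double eed;    // passive elastance scale at unstressed volume (mmHg/mL)
  double v0a;    // active unstressed volume (mL)
  double v0p;    // passive unstressed volume (mL)
  double vs;     // passive curvature volume (mL)
  double tau;    // relaxation time constant (s)
  double onset;  // activation onset, fraction of cycle
  double tp;     // time to peak activation, fraction of cycle
};

struct Valve {
  double area;   // anatomical open area (cm^2)
  double leak;   // fraction of area left open against the gradient
  double sten;   // fractional narrowing of forward area
  double rlin;   // series linear resistance (mmHg s/mL)
  double len;    // effective blood-column length (cm); 0 = quasi-steady
};

struct Model {
  double T;            // cycle length (s)
  Chamber ch[4];       // LA, LV, RA, RV
  Valve va[4];         // MV, AV, TV, PV
  // windkessel beds
  double c_ao, v0_ao, c_sv, v0_sv, c_pa, v0_pa, c_pv, v0_pv;
  double r_sys, r_vs, r_pul, r_vp;
  // shunt: 0 none, 1 atrial (LA-RA), 2 ventricular (LV-RV)
  int shunt_loc;
  double shunt_area, shunt_rlin;
};

static inline double activation(double t, const Model& m, const Chamber& ch) {
  double u = t / m.T - ch.onset;
  u -= std::floor(u);  // wrap to [0, 1)
  double tc = u * m.T, tp = ch.tp * m.T;
  if (tc < tp) return 0.5 * (1.0 - std::cos(M_PI * tc / tp));
  return std::exp(-(tc - tp) / ch.tau);
}

static inline double chamber_pressure(double v, double act, const Chamber& ch) {
  double pact = act * ch.emax * (v - ch.v0a);
  double ppas = ch.eed * ch.vs * (std::exp((v - ch.v0p) / ch.vs) - 1.0);
  return pact + ppas;
}

// Bernoulli orifice with linear series term: dp = rlin*q + K*q|q|.
static inline double orifice_flow(double dp, double area_cm2, double rlin) {
  if (area_cm2 <= 0.0) return 0.0;
  double a = area_cm2 * 1e-4;                                  // m^2
  double K = RHO_BLOOD / (2.0 * a * a) * 1e-12 / PA_PER_MMHG;  // mmHg/(mL/s)^2
  double ad = std::fabs(dp);
  double q = (std::sqrt(rlin * rlin + 4.0 * K * ad) - rlin) / (2.0 * K);
  return dp >= 0.0 ? q : -q;
}

static inline double valve_area_now(const Valve& v, double dp) {
  return dp >= 0.0 ? v.area * (1.0 - v.sten) : v.area * v.leak;
}

// Inertial valve: L dq/dt = dp - rlin q - K q|q|, with the orifice
// coefficient and inertance taken at the current flow-direction area.
// The AV valves carry inertance (len > 0) so that peak inflow coincides
// with the zero crossing of the transvalvular gradient, the trigger
// moment of the vibration model.
static inline double valve_dq(const Valve& va, double dp, double q,
                              double* area_now) {
  double a_fwd = va.area * (1.0 - va.sten);
  double a_leak = va.area * va.leak;
  double a = (q >= 0.0) ? a_fwd : (a_leak > 0.0 ? a_leak : a_fwd);
  if (area_now) *area_now = (q >= 0.0) ? a_fwd : a_leak;
  double a_m2 = a * 1e-4;
  double K = RHO_BLOOD / (2.0 * a_m2 * a_m2) * 1e-12 / PA_PER_MMHG;
  double L = RHO_BLOOD * (va.len * 0.01) / a_m2 * 1e-6 / PA_PER_MMHG;
  return (dp - va.rlin * q - K * q * std::fabs(q)) / L;
}

// out (optional, length >= 18): p_la p_lv p_ra p_rv p_ao p_pu
//                               q_mv q_tv q_av q_pv q_shunt
//                               a_mv a_tv a_av a_pv p_sv p_pvn act_lv
static void deriv(double t, const double* v, const Model& m, double* dv,
                  double* out) {
  double p[4];
  double act_lv = 0.0;
  for (int i = 0; i < 4; i++) {
    double a = activation(t, m, m.ch[i]);
    if (i == 1) act_lv = a;
    p[i] = chamber_pressure(v[i], a, m.ch[i]);
  }
  double p_ao = (v[4] - m.v0_ao) / m.c_ao;
  double p_sv = (v[5] - m.v0_sv) / m.c_sv;
  double p_pa = (v[6] - m.v0_pa) / m.c_pa;
  double p_pv = (v[7] - m.v0_pv) / m.c_pv;

  double dp_mv = p[0] - p[1];
  double dp_av = p[1] - p_ao;
  double dp_tv = p[2] - p[3];
  double dp_pvv = p[3] - p_pa;
  // AV valves are inertial states (v[8] = q_mv, v[9] = q_tv);
  // semilunar valves stay quasi-steady.
  double a_mv, a_tv;
  double q_mv = v[8], q_tv = v[9];
  double dq_mv = valve_dq(m.va[0], dp_mv, q_mv, &a_mv);
  double dq_tv = valve_dq(m.va[2], dp_tv, q_tv, &a_tv);
  double a_av = valve_area_now(m.va[1], dp_av);
  double a_pv = valve_area_now(m.va[3], dp_pvv);
  double q_av = orifice_flow(dp_av, a_av, m.va[1].rlin);
  double q_pv = orifice_flow(dp_pvv, a_pv, m.va[3].rlin);

  double q_sys = (p_ao - p_sv) / m.r_sys;
  double q_vs  = (p_sv - p[2]) / m.r_vs;
  double q_pul = (p_pa - p_pv) / m.r_pul;
  double q_vp  = (p_pv - p[0]) / m.r_vp;

  double q_sh = 0.0;  // positive = left-to-right
  if (m.shunt_loc == 1)
    q_sh = orifice_flow(p[0] - p[2], m.shunt_area, m.shunt_rlin);
  else if (m.shunt_loc == 2)
    q_sh = orifice_flow(p[1] - p[3], m.shunt_area, m.shunt_rlin);

  dv[0] = q_vp - q_mv - (m.shunt_loc == 1 ? q_sh : 0.0);
  dv[1] = q_mv - q_av - (m.shunt_loc == 2 ? q_sh : 0.0);
  dv[2] = q_vs - q_tv + (m.shunt_loc == 1 ? q_sh : 0.0);
  dv[3] = q_tv - q_pv + (m.shunt_loc == 2 ? q_sh : 0.0);
  dv[4] = q_av - q_sys;
  dv[5] = q_sys - q_vs;
  dv[6] = q_pv - q_pul;
  dv[7] = q_pul - q_vp;
  dv[8] = dq_mv;
  dv[9] = dq_tv;

  if (out) {
    out[0] = p[0]; out[1] = p[1]; out[2] = p[2]; out[3] = p[3];
    out[4] = p_ao; out[5] = p_pa;
    out[6] = q_mv; out[7] = q_tv; out[8] = q_av; out[9] = q_pv;
    out[10] = q_sh;
    out[11] = a_mv; out[12] = a_tv; out[13] = a_av; out[14] = a_pv;
    out[15] = p_sv; out[16] = p_pv; out[17] = act_lv;
  }
}

static const int NS = 10;

static bool rk4_step(double t, double dt, double* v, const Model& m) {
  double k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS];
  deriv(t, v, m, k1, 0);
  for (int i = 0; i < NS; i++) tmp[i] = v[i] + 0.5 * dt * k1[i];
  deriv(t + 0.5 * dt, tmp, m, k2, 0);
  for (int i = 0; i < NS; i++) tmp[i] = v[i] + 0.5 * dt * k2[i];
  deriv(t + 0.5 * dt, tmp, m, k3, 0);
  for (int i = 0; i < NS; i++) tmp[i] = v[i] + dt * k3[i];
  deriv(t + dt, tmp, m, k4, 0);
  for (int i = 0; i < NS; i++) {
    v[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (!std::isfinite(v[i])) return false;
    if (i < 8 && v[i] <= 0.0) return false;
  }
  // a competent AV valve cannot carry retrograde flow
  if (m.va[0].leak <= 0.0 && v[8] < 0.0) v[8] = 0.0;
  if (m.va[2].leak <= 0.0 && v[9] < 0.0) v[9] = 0.0;
  return true;
}

static Model parse_model(const List& pars) {
  Model m;
  m.T = as<double>(pars["T"]);
  List chs = pars["chambers"];
  const char* chn[4] = {"la", "lv", "ra", "rv"};
  for (int i = 0; i < 4; i++) {
    NumericVector c = chs[chn[i]];
    m.ch[i].emax = c["emax"]; m.ch[i].eed = c["eed"];
    m.ch[i].v0a = c["v0a"];   m.ch[i].v0p = c["v0p"];
    m.ch[i].vs = c["vs"];     m.ch[i].tau = c["tau"];
    m.ch[i].onset = c["onset"]; m.ch[i].tp = c["tp"];
  }
  List vas = pars["valves"];
  const char* van[4] = {"mv", "av", "tv", "pv"};
  for (int i = 0; i < 4; i++) {
    NumericVector v = vas[van[i]];
    m.va[i].area = v["area"]; m.va[i].leak = v["leak"];
    m.va[i].sten = v["sten"]; m.va[i].rlin = v["rlin"];
    m.va[i].len = v["len"];
  }
  NumericVector b = pars["beds"];
  m.c_ao = b["c_ao"]; m.v0_ao = b["v0_ao"];
  m.c_sv = b["c_sv"]; m.v0_sv = b["v0_sv"];
  m.c_pa = b["c_pa"]; m.v0_pa = b["v0_pa"];
  m.c_pv = b["c_pv"]; m.v0_pv = b["v0_pv"];
  m.r_sys = b["r_sys"]; m.r_vs = b["r_vs"];
  m.r_pul = b["r_pul"]; m.r_vp = b["r_vp"];
  NumericVector s = pars["shunt"];
  m.shunt_loc = (int) s["loc"];
  m.shunt_area = s["area"]; m.shunt_rlin = s["rlin"];
  return m;
}

// [[Rcpp::export]]
List cpp_simulate(List pars, NumericVector state0, int max_beats, double tol,
                  bool record_beat, double dt_int) {
  Model m = parse_model(pars);
  int n_ms = (int) std::lround(m.T * 1000.0);
  int n_sub = (int) std::lround(0.001 / dt_int);
  if (n_sub < 1) n_sub = 1;
  double dt = 0.001 / n_sub;

  double v[NS], prev[NS];
  for (int i = 0; i < NS; i++) v[i] = state0[i];

  bool converged = false, blew_up = false;
  double delta = NA_REAL;
  int beats = 0;
  for (int b = 0; b < max_beats && !blew_up; b++) {
    for (int i = 0; i < NS; i++) prev[i] = v[i];
    for (int ms = 0; ms < n_ms && !blew_up; ms++) {
      for (int s = 0; s < n_sub; s++) {
        double t = ms * 0.001 + s * dt;
        if (!rk4_step(t, dt, v, m)) { blew_up = true; break; }
      }
    }
    beats = b + 1;
    delta = 0.0;
    for (int i = 0; i < NS; i++) {
      double d = std::fabs(v[i] - prev[i]) / (std::fabs(prev[i]) + 1.0);
      if (d > delta) delta = d;
    }
    if (b >= 1 && delta < tol) { converged = true; break; }
  }

  SEXP rec = R_NilValue;
  if (record_beat && !blew_up) {
    NumericMatrix M(n_ms, 25);
    double out[18], dv[NS];
    for (int ms = 0; ms < n_ms && !blew_up; ms++) {
      double t = ms * 0.001;
      deriv(t, v, m, dv, out);
      M(ms, 0) = (double) ms;
      for (int j = 0; j < 6; j++) M(ms, 1 + j) = out[j];        // pressures
      for (int j = 0; j < 4; j++) M(ms, 7 + j) = v[j];          // chamber vols
      for (int j = 0; j < 5; j++) M(ms, 11 + j) = out[6 + j];   // flows
      for (int j = 0; j < 4; j++) M(ms, 16 + j) = out[11 + j];  // areas
      for (int j = 0; j < 4; j++) M(ms, 20 + j) = v[4 + j];     // bed vols
      M(ms, 24) = out[17];                                      // LV activation
      for (int s = 0; s < n_sub; s++) {
        double tt = ms * 0.001 + s * dt;
        if (!rk4_step(tt, dt, v, m)) { blew_up = true; break; }
      }
    }
    colnames(M) = CharacterVector::create(
      "t_ms", "p_la", "p_lv", "p_ra", "p_rv", "p_ao", "p_pu",
      "v_la", "v_lv", "v_ra", "v_rv",
      "q_mv", "q_tv", "q_av", "q_pv", "q_shunt",
      "a_mv", "a_tv", "a_av", "a_pv",
      "v_ao", "v_sv", "v_pa", "v_pvn", "act_lv");
    rec = M;
  }

  NumericVector fin(NS);
  for (int i = 0; i < NS; i++) fin[i] = v[i];
  fin.names() = CharacterVector::create("la", "lv", "ra", "rv",
                                        "ao", "sv", "pa", "pvn",
                                        "q_mv", "q_tv");
  return List::create(_["state"] = fin, _["beats"] = beats,
                      _["converged"] = converged, _["delta"] = delta,
                      _["failed"] = blew_up, _["record"] = rec);
}
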