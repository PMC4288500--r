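// Single-compartment conductance-based CA3 pyramidal-neuron burst model.
//
// Hodgkin-Huxley-style kinetics: m3h Na+, n4 delayed rectifier, a*b A-type,
// slowly activating T-type Ca2+ gate n (no inactivation; it is the slow
// autocatalytic variable of the burster), Ca2+-gated slow KCa gate o (the slow
// negative-feedback variable), Boltzmann M-current gate w, very slow Ca2+-gated
// AHP gate q, and a single well-mixed Ca2+ pool.  Ca2+ currents use a
// GHK (constant-field) driving term normalized to external Ca2+ so that
// conductances stay in mS/cm^2.  All rate-function constants arrive from R in
// one named vector (see kinetics_constants()) so the kinetics set is pinned in
// a single place on the R side.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Kin {
  double vt, ca_ext, ca_drive;
  double m_th, m_k, m_tau;
  double h_th, h_k, h_tau0, h_tauA, h_tth, h_tk;
  double nk_th, nk_k, nk_tau0, nk_tauA, nk_tth, nk_tk;
  double a_th, a_k, a_tau;
  double b_th, b_k, b_tau;
  double n_th, n_k, n_tau0, n_tauA, n_tth, n_tk;
  double o_kd, o_hill, o_tau;
  double w_th, w_k, w_tau;
  double q_kd, q_hill, q_tau;
  double ca_k, ca_tau, ca_rest;
  double mL_th, mL_k, mN_th, mN_k;
};

struct Par {
  double cm, gna, gcat, gcal, gcan, gkdr, ga, gm, gkca, gkahp, gleak;
  double vna, vk, vleak;
  double iapp, stim_start, stim_dur;
};

static inline double boltz(double v, double th, double k) {
  return 1.0 / (1.0 + std::exp(-(v - th) / k));
}

// normalized GHK driving term (mV-like); ca_i in uM, ca_ext in mM
static inline double ghk_drive(double v, double ca_i, double ca_ext, double vt) {
  double phi = 2.0 * v / vt;
  double r = (ca_i * 1e-3) / ca_ext;
  if (std::fabs(phi) < 1e-6) return (vt / 2.0) * (r - 1.0);
  double e = std::exp(-phi);
  return v * (r - e) / (1.0 - e);
}

static Kin read_kin(const NumericVector& k) {
  Kin q;
  q.vt = k["vt"]; q.ca_ext = k["ca_ext"]; q.ca_drive = k["ca_drive"];
  q.m_th = k["m_th"]; q.m_k = k["m_k"]; q.m_tau = k["m_tau"];
  q.h_th = k["h_th"]; q.h_k = k["h_k"]; q.h_tau0 = k["h_tau0"];
  q.h_tauA = k["h_tauA"]; q.h_tth = k["h_tth"]; q.h_tk = k["h_tk"];
  q.nk_th = k["nk_th"]; q.nk_k = k["nk_k"]; q.nk_tau0 = k["nk_tau0"];
  q.nk_tauA = k["nk_tauA"]; q.nk_tth = k["nk_tth"]; q.nk_tk = k["nk_tk"];
  q.a_th = k["a_th"]; q.a_k = k["a_k"]; q.a_tau = k["a_tau"];
  q.b_th = k["b_th"]; q.b_k = k["b_k"]; q.b_tau = k["b_tau"];
  q.n_th = k["n_th"]; q.n_k = k["n_k"]; q.n_tau0 = k["n_tau0"];
  q.n_tauA = k["n_tauA"]; q.n_tth = k["n_tth"]; q.n_tk = k["n_tk"];
  q.o_kd = k["o_kd"]; q.o_hill = k["o_hill"]; q.o_tau = k["o_tau"];
  q.w_th = k["w_th"]; q.w_k = k["w_k"]; q.w_tau = k["w_tau"];
  q.q_kd = k["q_kd"]; q.q_hill = k["q_hill"]; q.q_tau = k["q_tau"];
  q.ca_k = k["ca_k"]; q.ca_tau = k["ca_tau"]; q.ca_rest = k["ca_rest"];
  q.mL_th = k["mL_th"]; q.mL_k = k["mL_k"];
  q.mN_th = k["mN_th"]; q.mN_k = k["mN_k"];
  return q;
}

static Par read_par(const NumericVector& p) {
  Par q;
  q.cm = p["cm"];
  q.gna = p["g_na"]; q.gcat = p["g_cat"]; q.gcal = p["g_cal"];
  q.gcan = p["g_can"]; q.gkdr = p["g_kdr"]; q.ga = p["g_a"];
  q.gm = p["g_m"]; q.gkca = p["g_kca"]; q.gkahp = p["g_kahp"];
  q.gleak = p["g_leak"];
  q.vna = p["v_na"]; q.vk = p["v_k"]; q.vleak = p["v_leak"];
  q.iapp = p["i_app"]; q.stim_start = p["stim_start"]; q.stim_dur = p["stim_dur"];
  return q;
}

// state order: V m h nk a b n o w q ca
static const int NS = 11;

static inline double hill_ca(double ca, double kd, double h) {
  double x = std::pow(ca / kd, h);
  return x / (1.0 + x);
}

// ionic current sum (positive outward), given full state
static inline double current_sum(const double* s, const Par& p, const Kin& K,
                                 double* cur /* may be null, length 10 */) {
  double V = s[0];
  double drv = ghk_drive(V, s[10], K.ca_ext, K.vt) / K.ca_drive;
  double mL = boltz(V, K.mL_th, K.mL_k);
  double mN = boltz(V, K.mN_th, K.mN_k);
  double ina  = p.gna * s[1]*s[1]*s[1]*s[2] * (V - p.vna);
  double icat = p.gcat * s[6] * drv;
  double ical = p.gcal * mL*mL * drv;
  double ican = p.gcan * mN*mN * drv;
  double ikdr = p.gkdr * s[3]*s[3]*s[3]*s[3] * (V - p.vk);
  double ia   = p.ga * s[4] * s[5] * (V - p.vk);
  double im   = p.gm * s[8] * (V - p.vk);
  double ikca = p.gkca * s[7] * (V - p.vk);
  double iahp = p.gkahp * s[9] * (V - p.vk);
  double ilk  = p.gleak * (V - p.vleak);
  if (cur) {
    cur[0]=ina; cur[1]=icat; cur[2]=ical; cur[3]=ican; cur[4]=ikdr;
    cur[5]=ia;  cur[6]=im;   cur[7]=ikca; cur[8]=iahp; cur[9]=ilk;
  }
  return ina + icat + ical + ican + ikdr + ia + im + ikca + iahp + ilk;
}

// full right-hand side; freeze: bitmask 1 = n, 2 = o, 4 = Ca
static void rhs(double t, const double* s, double* ds, const Par& p,
                const Kin& K, int freeze) {
  double V = s[0];
  double isum = current_sum(s, p, K, nullptr);
  double iapp = (t >= p.stim_start && t < p.stim_start + p.stim_dur) ? p.iapp : 0.0;
  ds[0] = (-isum + iapp) / p.cm;
  ds[1] = (boltz(V, K.m_th, K.m_k) - s[1]) / K.m_tau;
  double zh = (V - K.h_tth) / K.h_tk;
  double tau_h = K.h_tau0 + K.h_tauA * std::exp(-0.5 * zh * zh);
  ds[2] = (1.0 / (1.0 + std::exp((V - K.h_th) / K.h_k)) - s[2]) / tau_h;
  double tau_nk = K.nk_tau0 + K.nk_tauA / (1.0 + std::exp((V - K.nk_tth) / K.nk_tk));
  ds[3] = (boltz(V, K.nk_th, K.nk_k) - s[3]) / tau_nk;
  ds[4] = (boltz(V, K.a_th, K.a_k) - s[4]) / K.a_tau;
  ds[5] = (1.0 / (1.0 + std::exp((V - K.b_th) / K.b_k)) - s[5]) / K.b_tau;
  double tau_n = K.n_tau0 + K.n_tauA * boltz(V, K.n_tth, K.n_tk);
  ds[6] = (freeze & 1) ? 0.0 : (boltz(V, K.n_th, K.n_k) - s[6]) / tau_n;
  ds[7] = (freeze & 2) ? 0.0 : (hill_ca(s[10], K.o_kd, K.o_hill) - s[7]) / K.o_tau;
  ds[8] = (boltz(V, K.w_th, K.w_k) - s[8]) / K.w_tau;
  ds[9] = (hill_ca(s[10], K.q_kd, K.q_hill) - s[9]) / K.q_tau;
  if (freeze & 4) {
    ds[10] = 0.0;
  } else {
    double drv = ghk_drive(V, s[10], K.ca_ext, K.vt) / K.ca_drive;
    double mL = boltz(V, K.mL_th, K.mL_k);
    double mN = boltz(V, K.mN_th, K.mN_k);
    double ica = p.gcat * s[6] * drv + p.gcal * mL*mL * drv + p.gcan * mN*mN * drv;
    ds[10] = -K.ca_k * ica - (s[10] - K.ca_rest) / K.ca_tau;
  }
}

// [[Rcpp::export]]
NumericVector default_state_cpp(NumericVector par, NumericVector kin, double v0,
                                double ca0) {
  Kin K = read_kin(kin);
  NumericVector s(NS);
  s[0] = v0;
  s[1] = boltz(v0, K.m_th, K.m_k);
  s[2] = 1.0 / (1.0 + std::exp((v0 - K.h_th) / K.h_k));
  s[3] = boltz(v0, K.nk_th, K.nk_k);
  s[4] = boltz(v0, K.a_th, K.a_k);
  s[5] = 1.0 / (1.0 + std::exp((v0 - K.b_th) / K.b_k));
  s[6] = boltz(v0, K.n_th, K.n_k);
  s[7] = hill_ca(ca0, K.o_kd, K.o_hill);
  s[8] = boltz(v0, K.w_th, K.w_k);
  s[9] = hill_ca(ca0, K.q_kd, K.q_hill);
  s[10] = ca0;
  s.attr("names") = CharacterVector::create("V","m","h","nk","a","b","n","o",
                                            "w","q","ca");
  return s;
}

// [[Rcpp::export]]
List sim_neuron_cpp(NumericVector par, NumericVector kin, NumericVector state0,
                    double dt, double duration, int record_every, int method,
                    int freeze) {
  Par p = read_par(par);
  Kin K = read_kin(kin);
  if (state0.size() != NS) stop("state vector must have %d elements", NS);
  double s[NS], ds[NS], k1[NS], k2[NS], k3[NS], k4[NS], tmp[NS];
  for (int i = 0; i < NS; ++i) s[i] = state0[i];

  long nstep = (long)std::llround(duration / dt);
  long nrec = nstep / record_every + 1;
  NumericMatrix out(nrec, NS + 2);  // t, states..., dVdt
  long r = 0;
  for (long step = 0; step <= nstep; ++step) {
    double t = step * dt;
    if (step % record_every == 0 && r < nrec) {
      rhs(t, s, ds, p, K, freeze);
      out(r, 0) = t;
      for (int i = 0; i < NS; ++i) out(r, i + 1) = s[i];
      out(r, NS + 1) = ds[0];
      ++r;
    }
    if (step == nstep) break;
    if (std::fabs(s[0]) > 200.0)
      stop("numerical blow-up: |V| > 200 mV at t = %f ms", t);
    if (method == 0) {  // explicit Euler
      rhs(t, s, ds, p, K, freeze);
      for (int i = 0; i < NS; ++i) s[i] += dt * ds[i];
    } else {            // classical RK4
      rhs(t, s, k1, p, K, freeze);
      for (int i = 0; i < NS; ++i) tmp[i] = s[i] + 0.5 * dt * k1[i];
      rhs(t + 0.5 * dt, tmp, k2, p, K, freeze);
      for (int i = 0; i < NS; ++i) tmp[i] = s[i] + 0.5 * dt * k2[i];
      rhs(t + 0.5 * dt, tmp, k3, p, K, freeze);
      for (int i = 0; i < NS; ++i) tmp[i] = s[i] + dt * k3[i];
      rhs(t + dt, tmp, k4, p, K, freeze);
      for (int i = 0; i < NS; ++i)
        s[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    }
    if (s[10] < 0.0) s[10] = 0.0;
  }
  colnames(out) = CharacterVector::create("time_ms","V","m","h","nk","a","b",
                                          "n","o","w","q","ca","dVdt");
  return List::create(_["trace"] = out);
}

// quasi-steady membrane current balance of the fast subsystem:
// every gate at its voltage steady state except frozen n, o; Ca fixed.
// Returns F(V) = -(sum of currents) (I_app = 0), so dV/dt = F/Cm.
// [[Rcpp::export]]
NumericVector fast_balance_cpp(NumericVector v_grid, NumericVector par,
                               NumericVector kin, double n, double o,
                               double ca) {
  Par p = read_par(par);
  Kin K = read_kin(kin);
  int nv = v_grid.size();
  NumericVector out(nv);
  double s[NS];
  for (int j = 0; j < nv; ++j) {
    double V = v_grid[j];
    s[0] = V;
    s[1] = boltz(V, K.m_th, K.m_k);
    s[2] = 1.0 / (1.0 + std::exp((V - K.h_th) / K.h_k));
    s[3] = boltz(V, K.nk_th, K.nk_k);
    s[4] = boltz(V, K.a_th, K.a_k);
    s[5] = 1.0 / (1.0 + std::exp((V - K.b_th) / K.b_k));
    s[6] = n;
    s[7] = o;
    s[8] = boltz(V, K.w_th, K.w_k);
    s[9] = hill_ca(ca, K.q_kd, K.q_hill);
    s[10] = ca;
    out[j] = -current_sum(s, p, K, nullptr);
  }
  return out;
}

// per-current reconstruction at recorded states (columns of sim output)
// [[Rcpp::export]]
NumericMatrix currents_cpp(NumericMatrix trace, NumericVector par,
                           NumericVector kin) {
  Par p = read_par(par);
  Kin K = read_kin(kin);
  int nr = trace.nrow();
  NumericMatrix out(nr, 10);
  double s[NS], cur[10];
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < NS; ++j) s[j] = trace(i, j + 1);
    current_sum(s, p, K, cur);
    for (int j = 0; j < 10; ++j) out(i, j) = cur[j];
  }
  colnames(out) = CharacterVector::create("I_Na","I_CaT","I_CaL","I_CaN",
                                          "I_KDR","I_A","I_M","I_KCa","I_AHP",
                                          "I_Leak");
  return out;
}
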