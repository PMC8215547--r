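// Two-compartment Pinsky-Rinzel neuron: fixed-step integrator used by the
// biophysical layer. Voltages are handled in the shifted convention of the
// original model (leak reversal = 0); the R layer maps to absolute mV by
// adding each cell's fitted leak reversal E_L.
//
// State layout: [Vs, Vd, h, n, s, c, q, Ca]
// Parameter layout (see R/pr_params.R, must stay in sync):
//   [cm, gL, gNa, gDR, gAHP, gCa, gC, gc, p, Vsyn_shift, thr_shift]
// Units: mV, ms, mS/cm^2, uF/cm^2, uA/cm^2.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int P_CM = 0, P_GL = 1, P_GNA = 2, P_GDR = 3, P_GAHP = 4,
                 P_GCA = 5, P_GC = 6, P_GCPL = 7, P_P = 8, P_VSYN = 9,
                 P_THR = 10, P_NASH = 11;
static const int NPAR = 12;

// x / (exp(x/k) - 1) with removable singularity at x = 0
static inline double vtrap(double x, double k) {
  if (std::fabs(x / k) < 1e-6) return k * (1.0 - x / (2.0 * k));
  return x / (std::exp(x / k) - 1.0);
}

static inline double alpha_m(double v) { return 0.32 * vtrap(13.1 - v, 4.0); }
static inline double beta_m(double v)  { return 0.28 * vtrap(v - 40.1, 5.0); }
static inline double alpha_n(double v) { return 0.016 * vtrap(35.1 - v, 5.0); }
static inline double beta_n(double v)  { return 0.25 * std::exp(0.5 - 0.025 * v); }
static inline double alpha_h(double v) { return 0.128 * std::exp((17.0 - v) / 18.0); }
static inline double beta_h(double v)  { return 4.0 / (1.0 + std::exp((40.0 - v) / 5.0)); }
static inline double alpha_s(double v) { return 1.6 / (1.0 + std::exp(-0.072 * (v - 65.0))); }
static inline double beta_s(double v)  { return 0.02 * vtrap(v - 51.1, 5.0); }
static inline double alpha_c(double v) {
  if (v <= 50.0) return std::exp((v - 10.0) / 11.0 - (v - 6.5) / 27.0) / 18.975;
  return 2.0 * std::exp((6.5 - v) / 27.0);
}
static inline double beta_c(double v) {
  if (v <= 50.0) return 2.0 * std::exp((6.5 - v) / 27.0) - alpha_c(v);
  return 0.0;
}

struct Deriv {
  double dVs, dVd, dh, dn, ds, dc, dq, dCa;
};

// events: n x 3 (onset ms, peak conductance density mS/cm^2 on dendrite, tau ms)
static inline double syn_gdens(double t, const double* ev, int nev) {
  double g = 0.0;
  for (int i = 0; i < nev; ++i) {
    double u = (t - ev[3 * i]) / ev[3 * i + 2];
    if (u > 0.0) g += ev[3 * i + 1] * u * std::exp(1.0 - u);
  }
  return g;
}

static inline Deriv pr_deriv(const double* s, const double* p,
                             double is_dens, double gsyn) {
  const double Vs = s[0], Vd = s[1], h = s[2], n = s[3], ss = s[4],
               c = s[5], q = s[6], Ca = s[7];
  const double VNa = 120.0, VCa = 140.0, VK = -15.0;
  // Na activation evaluated at Vs - na_shift: uniform depolarizing shift of
  // the activation curve that keeps the high-gNa fitted cells tonically
  // stable at rest (see methods vignette)
  double vm = Vs - p[P_NASH];
  double am = alpha_m(vm), bm = beta_m(vm);
  double minf = am / (am + bm);
  double chi = Ca < 250.0 ? Ca / 250.0 : 1.0;
  double INa = p[P_GNA] * minf * minf * h * (Vs - VNa);
  double IDR = p[P_GDR] * n * (Vs - VK);
  double ICa = p[P_GCA] * ss * ss * (Vd - VCa);
  double IAHP = p[P_GAHP] * q * (Vd - VK);
  double IKC = p[P_GC] * c * chi * (Vd - VK);
  Deriv d;
  d.dVs = (-p[P_GL] * Vs - INa - IDR +
           p[P_GCPL] * (Vd - Vs) / p[P_P] + is_dens) / p[P_CM];
  d.dVd = (-p[P_GL] * Vd - ICa - IAHP - IKC +
           p[P_GCPL] * (Vs - Vd) / (1.0 - p[P_P]) +
           gsyn * (p[P_VSYN] - Vd)) / p[P_CM];
  d.dh = alpha_h(Vs) * (1.0 - h) - beta_h(Vs) * h;
  d.dn = alpha_n(Vs) * (1.0 - n) - beta_n(Vs) * n;
  d.ds = alpha_s(Vd) * (1.0 - ss) - beta_s(Vd) * ss;
  d.dc = alpha_c(Vd) * (1.0 - c) - beta_c(Vd) * c;
  double aq = 0.00002 * Ca; if (aq > 0.01) aq = 0.01;
  d.dq = aq * (1.0 - q) - 0.001 * q;
  d.dCa = -0.13 * ICa - 0.075 * Ca;
  return d;
}

static inline void clamp_gates(double* s) {
  for (int i = 2; i <= 6; ++i) {
    if (s[i] < 0.0) s[i] = 0.0;
    if (s[i] > 1.0) s[i] = 1.0;
  }
  if (s[7] < 0.0) s[7] = 0.0;
}

// Heun (RK2) step; returns false on numerical blow-up
static inline bool pr_step(double* s, const double* p, double t, double dt,
                           double is0, double is1, double g0, double g1) {
  Deriv k1 = pr_deriv(s, p, is0, g0);
  double tmp[8];
  tmp[0] = s[0] + dt * k1.dVs; tmp[1] = s[1] + dt * k1.dVd;
  tmp[2] = s[2] + dt * k1.dh;  tmp[3] = s[3] + dt * k1.dn;
  tmp[4] = s[4] + dt * k1.ds;  tmp[5] = s[5] + dt * k1.dc;
  tmp[6] = s[6] + dt * k1.dq;  tmp[7] = s[7] + dt * k1.dCa;
  clamp_gates(tmp);
  Deriv k2 = pr_deriv(tmp, p, is1, g1);
  s[0] += 0.5 * dt * (k1.dVs + k2.dVs);
  s[1] += 0.5 * dt * (k1.dVd + k2.dVd);
  s[2] += 0.5 * dt * (k1.dh + k2.dh);
  s[3] += 0.5 * dt * (k1.dn + k2.dn);
  s[4] += 0.5 * dt * (k1.ds + k2.ds);
  s[5] += 0.5 * dt * (k1.dc + k2.dc);
  s[6] += 0.5 * dt * (k1.dq + k2.dq);
  s[7] += 0.5 * dt * (k1.dCa + k2.dCa);
  clamp_gates(s);
  return std::fabs(s[0]) <= 1000.0 && std::fabs(s[1]) <= 1000.0;
}

struct SimResult {
  int count;
  double first_spike;
  std::vector<double> spike_times;
};

// Core run over [0, t_total]; records spikes as strict upward crossings of
// thr with a refractory guard. Optionally fills trace vectors.
static SimResult run_sim(double* s, const double* p, double dt, double t_total,
                         double inj_amp, double inj_on, double inj_off,
                         const double* ev, int nev, double refractory,
                         bool record, std::vector<double>* tr_t,
                         std::vector<double>* tr_vs, std::vector<double>* tr_vd,
                         bool stop_first = false) {
  int nstep = (int)std::round(t_total / dt);
  double thr = p[P_THR];
  SimResult res; res.count = 0; res.first_spike = NA_REAL;
  double last_spike = -1e9;
  double prev_vs = s[0];
  if (record) {
    tr_t->push_back(0.0); tr_vs->push_back(s[0]); tr_vd->push_back(s[1]);
  }
  for (int i = 0; i < nstep; ++i) {
    double t0 = i * dt, t1 = (i + 1) * dt;
    double is0 = (t0 >= inj_on && t0 < inj_off) ? inj_amp : 0.0;
    double is1 = (t1 >= inj_on && t1 < inj_off) ? inj_amp : 0.0;
    double g0 = nev ? syn_gdens(t0, ev, nev) : 0.0;
    double g1 = nev ? syn_gdens(t1, ev, nev) : 0.0;
    if (!pr_step(s, p, t0, dt, is0, is1, g0, g1))
      stop("pr integration diverged (|V| > 1000 mV) at t = %f ms", t1);
    if (prev_vs <= thr && s[0] > thr && (t1 - last_spike) > refractory) {
      res.count += 1;
      if (res.count == 1) res.first_spike = t1;
      res.spike_times.push_back(t1);
      last_spike = t1;
      if (stop_first) {
        if (record) {
          tr_t->push_back(t1); tr_vs->push_back(s[0]); tr_vd->push_back(s[1]);
        }
        return res;
      }
    }
    prev_vs = s[0];
    if (record) {
      tr_t->push_back(t1); tr_vs->push_back(s[0]); tr_vd->push_back(s[1]);
    }
  }
  return res;
}

// [[Rcpp::export]]
NumericVector pr_rest_cpp(NumericVector prm, double dt, double t_settle) {
  if (prm.size() != NPAR) stop("bad parameter vector length");
  double s[8];
  double v0 = 0.0;
  s[0] = v0; s[1] = v0;
  s[2] = alpha_h(v0) / (alpha_h(v0) + beta_h(v0));
  s[3] = alpha_n(v0) / (alpha_n(v0) + beta_n(v0));
  s[4] = alpha_s(v0) / (alpha_s(v0) + beta_s(v0));
  s[5] = alpha_c(v0) / (alpha_c(v0) + beta_c(v0));
  s[6] = 0.0; s[7] = 0.0;
  run_sim(s, REAL(prm), dt, t_settle, 0.0, 0.0, 0.0, nullptr, 0, 1.0,
          false, nullptr, nullptr, nullptr);
  return NumericVector(s, s + 8);
}

// [[Rcpp::export]]
List pr_simulate_cpp(NumericVector prm, NumericVector state0, double dt,
                     double t_total, double inj_amp, double inj_onset,
                     double inj_dur, NumericMatrix events, double refractory,
                     bool return_trace) {
  if (prm.size() != NPAR) stop("bad parameter vector length");
  if (state0.size() != 8) stop("bad state vector length");
  if (events.ncol() != 3 && events.nrow() > 0) stop("events must be n x 3");
  double s[8];
  std::copy(state0.begin(), state0.end(), s);
  std::vector<double> tt, vs, vd;
  // events come in column-major; repack row-major for cache friendliness
  int nev = events.nrow();
  std::vector<double> ev(3 * nev);
  for (int i = 0; i < nev; ++i) {
    ev[3 * i] = events(i, 0); ev[3 * i + 1] = events(i, 1);
    ev[3 * i + 2] = events(i, 2);
    if (events(i, 2) <= 0) stop("synapse tau must be positive");
  }
  SimResult r = run_sim(s, REAL(prm), dt, t_total, inj_amp, inj_onset,
                        inj_onset + inj_dur, nev ? ev.data() : nullptr, nev,
                        refractory, return_trace, &tt, &vs, &vd);
  List out = List::create(
      _["count"] = r.count,
      _["first_spike"] = r.first_spike,
      _["spike_times"] = NumericVector(r.spike_times.begin(),
                                       r.spike_times.end()),
      _["state"] = NumericVector(s, s + 8));
  if (return_trace) {
    out["time"] = NumericVector(tt.begin(), tt.end());
    out["vs"] = NumericVector(vs.begin(), vs.end());
    out["vd"] = NumericVector(vd.begin(), vd.end());
  }
  return out;
}

// Did the post-synaptic neuron fire at least once? Early exit on first spike.
// [[Rcpp::export]]
bool pr_fires_cpp(NumericVector prm, NumericVector state0, double dt,
                  double t_total, NumericMatrix events, double refractory) {
  if (prm.size() != NPAR) stop("bad parameter vector length");
  double s[8];
  std::copy(state0.begin(), state0.end(), s);
  int nev = events.nrow();
  std::vector<double> ev(3 * nev);
  for (int i = 0; i < nev; ++i) {
    ev[3 * i] = events(i, 0); ev[3 * i + 1] = events(i, 1);
    ev[3 * i + 2] = events(i, 2);
  }
  SimResult r = run_sim(s, REAL(prm), dt, t_total, 0.0, 0.0, 0.0,
                        nev ? ev.data() : nullptr, nev, refractory,
                        false, nullptr, nullptr, nullptr, true);
  return r.count > 0;
}

// Hidden-layer binary responses for a batch of binary input vectors.
// X: n_img x n_in (0/1). For each image and each hidden neuron, the active
// inputs that are connected contribute one alpha event each; the hidden
// neuron fires if its soma crosses threshold within the window.
// conn: list (length n_hidden) of 0-based connected input indices.
// G: n_in x n_hidden peak conductance densities (mS/cm^2, per-post dendrite).
// TAU, DELAY: n_in x n_hidden synapse kinetics; spike_t: n_in pre spike times.
// PRM: n_hidden x NPAR; S0: n_hidden x 8 resting states.
// [[Rcpp::export]]
IntegerMatrix biophys_hidden_cpp(IntegerMatrix X, List conn, NumericMatrix G,
                                 NumericMatrix TAU, NumericMatrix DELAY,
                                 NumericVector spike_t, NumericMatrix PRM,
                                 NumericMatrix S0, double dt, double window,
                                 double refractory) {
  int n_img = X.nrow(), n_hidden = conn.size();
  IntegerMatrix H(n_img, n_hidden);
  std::vector<double> ev;
  for (int j = 0; j < n_hidden; ++j) {
    IntegerVector cj = conn[j];
    NumericVector prm = PRM(j, _);
    NumericVector s0 = S0(j, _);
    std::vector<double> pj(prm.begin(), prm.end());
    for (int img = 0; img < n_img; ++img) {
      ev.clear();
      for (int k = 0; k < cj.size(); ++k) {
        int m = cj[k];
        if (X(img, m)) {
          double onset = spike_t[m] + DELAY(m, j), tau = TAU(m, j);
          // alpha conductances with identical onset and tau add up;
          // merging keeps the per-step event loop short
          bool merged = false;
          for (size_t e = 0; e < ev.size(); e += 3) {
            if (ev[e] == onset && ev[e + 2] == tau) {
              ev[e + 1] += G(m, j);
              merged = true;
              break;
            }
          }
          if (!merged) {
            ev.push_back(onset);
            ev.push_back(G(m, j));
            ev.push_back(tau);
          }
        }
      }
      if (ev.empty()) { H(img, j) = 0; continue; }
      double s[8];
      std::copy(s0.begin(), s0.end(), s);
      SimResult r = run_sim(s, pj.data(), dt, window, 0.0, 0.0, 0.0,
                            ev.data(), (int)(ev.size() / 3), refractory,
                            false, nullptr, nullptr, nullptr, true);
      H(img, j) = r.count > 0 ? 1 : 0;
    }
    Rcpp::checkUserInterrupt();
  }
  return H;
}
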