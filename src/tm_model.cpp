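// Traub-Miles conductance-based model with a slow M-type adaptation current.
// Deterministic integration uses RK4; the stochastic system uses
// Euler-Maruyama. Spikes are upward crossings of V = 0 mV.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct TmPars {
  double C, I, gNa, gK, gL, gbar, ENa, EK, EL, tau_z;
};

// x / (1 - exp(-x/k)) with the analytic limit k + x/2 near x = 0, used by the
// gating rates whose printed expressions have removable singularities.
static inline double xoverexpm1(double x, double k) {
  const double u = x / k;
  if (std::fabs(u) < 1e-6) return k * (1.0 + 0.5 * u + u * u / 12.0);
  return x / (1.0 - std::exp(-u));
}

static inline double a_h(double V) { return 0.128 * std::exp(-(V + 50.0) / 18.0); }
static inline double a_m(double V) { return 0.32 * xoverexpm1(V + 54.0, 4.0); }
static inline double a_n(double V) { return 0.032 * xoverexpm1(V + 52.0, 5.0); }
static inline double b_h(double V) { return 4.0 / (1.0 + std::exp(-(V + 27.0) / 5.0)); }
static inline double b_m(double V) { return 0.28 * xoverexpm1(-(V + 27.0), 5.0); }
static inline double b_n(double V) { return 0.5 * std::exp(-(V + 57.0) / 40.0); }
static inline double hinf_z(double V) { return 1.0 / (1.0 + std::exp(-(V + 20.0) / 5.0)); }

// [[Rcpp::export]]
NumericVector tm_rates_cpp(double V) {
  return NumericVector::create(
    _["a_h"] = a_h(V), _["a_m"] = a_m(V), _["a_n"] = a_n(V),
    _["b_h"] = b_h(V), _["b_m"] = b_m(V), _["b_n"] = b_n(V),
    _["hinf_z"] = hinf_z(V));
}

// state: V, h, m, n, z ; eta_ext is an additional current (colored noise)
static inline void tm_deriv(const TmPars &p, const double *s, double eta_ext,
                            double *d) {
  const double V = s[0], h = s[1], m = s[2], n = s[3], z = s[4];
  const double Iion = p.gNa * h * m * m * m * (V - p.ENa) +
                      p.gL * (V - p.EL) + p.gK * n * n * n * n * (V - p.EK);
  const double Iadap = p.gbar * z * (V - p.EK);
  d[0] = (-Iion - Iadap + p.I + eta_ext) / p.C;
  d[1] = a_h(V) * (1.0 - h) - b_h(V) * h;
  d[2] = a_m(V) * (1.0 - m) - b_m(V) * m;
  d[3] = a_n(V) * (1.0 - n) - b_n(V) * n;
  d[4] = (hinf_z(V) - z) / p.tau_z;
}

// [[Rcpp::export]]
NumericVector tm_deriv_cpp(NumericVector pars, NumericVector state, double eta_ext) {
  TmPars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5],
              pars[6], pars[7], pars[8], pars[9]};
  double d[5];
  tm_deriv(p, state.begin(), eta_ext, d);
  return NumericVector::create(d[0], d[1], d[2], d[3], d[4]);
}

static inline void tm_rk4(const TmPars &p, double *s, double h) {
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  tm_deriv(p, s, 0.0, k1);
  for (int i = 0; i < 5; ++i) tmp[i] = s[i] + 0.5 * h * k1[i];
  tm_deriv(p, tmp, 0.0, k2);
  for (int i = 0; i < 5; ++i) tmp[i] = s[i] + 0.5 * h * k2[i];
  tm_deriv(p, tmp, 0.0, k3);
  for (int i = 0; i < 5; ++i) tmp[i] = s[i] + h * k3[i];
  tm_deriv(p, tmp, 0.0, k4);
  for (int i = 0; i < 5; ++i)
    s[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static TmPars tm_unpack(const NumericVector &pars) {
  TmPars p = {pars[0], pars[1], pars[2], pars[3], pars[4], pars[5],
              pars[6], pars[7], pars[8], pars[9]};
  return p;
}

static void tm_rest_state(const TmPars &p, double V0, double *s) {
  s[0] = V0;
  s[1] = a_h(V0) / (a_h(V0) + b_h(V0));
  s[2] = a_m(V0) / (a_m(V0) + b_m(V0));
  s[3] = a_n(V0) / (a_n(V0) + b_n(V0));
  s[4] = hinf_z(V0);
}

// Deterministic run: integrate until the inter-spike interval has settled,
// then return the period, the state and adaptation current at the final
// crossing, the maximum of I_adap over the final cycle, and the trajectory
// of the final cycle sampled every step (t measured from the crossing).
// [[Rcpp::export]]
List tm_limit_cycle_cpp(NumericVector pars, double dt, int n_spikes,
                        double max_time, bool step_protocol, double t_on) {
  TmPars p = tm_unpack(pars);
  const double I_full = p.I;
  double s[5];
  tm_rest_state(p, -70.0, s);
  double t = 0.0, last_cross = NA_REAL;
  std::vector<double> isis;
  std::vector<double> traj_t, traj_V, traj_z, traj_h, traj_m, traj_n;
  const int max_steps = (int)(max_time / dt);
  double z_cross = NA_REAL, V_prev = s[0];
  double iadap_max = 0.0;
  double cross_state[5] = {0, 0, 0, 0, 0};
  double s_prev[5];
  bool record = false;
  for (int i = 0; i < max_steps && (int)isis.size() < n_spikes; ++i) {
    if (step_protocol) p.I = (t >= t_on) ? I_full : 0.0;
    V_prev = s[0];
    for (int j = 0; j < 5; ++j) s_prev[j] = s[j];
    tm_rk4(p, s, dt);
    t += dt;
    if (record) {
      traj_t.push_back(t - last_cross);
      traj_V.push_back(s[0]); traj_h.push_back(s[1]); traj_m.push_back(s[2]);
      traj_n.push_back(s[3]); traj_z.push_back(s[4]);
      double ia = p.gbar * s[4] * (s[0] - p.EK);
      if (ia > iadap_max) iadap_max = ia;
    }
    if (V_prev < 0.0 && s[0] >= 0.0) {
      double frac = (0.0 - V_prev) / (s[0] - V_prev);
      double tc = t - dt + frac * dt;
      if (R_finite(last_cross)) {
        isis.push_back(tc - last_cross);
        // start recording one ISI before the final one
        if ((int)isis.size() == n_spikes - 1) {
          record = true;
          iadap_max = 0.0;
          traj_t.clear(); traj_V.clear(); traj_z.clear();
          traj_h.clear(); traj_m.clear(); traj_n.clear();
        }
      }
      last_cross = tc;
      // full state at the crossing by bisection on RK4 substeps
      {
        double lo = 0.0, hi = dt;
        double sm[5];
        for (int it = 0; it < 60; ++it) {
          double mid = 0.5 * (lo + hi);
          for (int j = 0; j < 5; ++j) sm[j] = s_prev[j];
          tm_rk4(p, sm, mid);
          if (sm[0] >= 0.0) hi = mid; else lo = mid;
        }
        for (int j = 0; j < 5; ++j) cross_state[j] = sm[j];
      }
      z_cross = cross_state[4];
    }
  }
  if ((int)isis.size() < 2)
    stop("excitable regime: no sustained firing within %g ms", max_time);
  double period = isis.back();
  double a_star = p.gbar * z_cross * (0.0 - p.EK) / p.C;
  return List::create(
    _["period"] = period,
    _["isis"] = wrap(isis),
    _["a_star_cross"] = a_star,
    _["a_star_max"] = iadap_max / p.C,
    _["z_cross"] = z_cross,
    _["state_cross"] = NumericVector(cross_state, cross_state + 5),
    _["traj"] = DataFrame::create(_["t"] = traj_t, _["V"] = traj_V,
                                  _["h"] = traj_h, _["m"] = traj_m,
                                  _["n"] = traj_n, _["z"] = traj_z));
}

// Time to the next upward crossing of V = 0 from a given state (deterministic).
// The crossing detector arms only once V has been below 0.
// [[Rcpp::export]]
double tm_cross_from_cpp(NumericVector pars, NumericVector state, double dt,
                         double max_time) {
  TmPars p = tm_unpack(pars);
  double s[5];
  for (int i = 0; i < 5; ++i) s[i] = state[i];
  double t = 0.0;
  bool armed = s[0] < 0.0;
  const int max_steps = (int)(max_time / dt);
  double s_prev[5];
  for (int i = 0; i < max_steps; ++i) {
    double V_prev = s[0];
    for (int j = 0; j < 5; ++j) s_prev[j] = s[j];
    tm_rk4(p, s, dt);
    t += dt;
    if (!armed && s[0] < 0.0) armed = true;
    else if (armed && V_prev < 0.0 && s[0] >= 0.0) {
      // refine the crossing by bisection on RK4 substeps from the pre-step
      // state (linear interpolation is too coarse during the fast upstroke)
      double pre[5];
      for (int j = 0; j < 5; ++j) pre[j] = s_prev[j];
      double lo = 0.0, hi = dt;
      for (int it = 0; it < 60; ++it) {
        double mid = 0.5 * (lo + hi);
        double sm[5];
        for (int j = 0; j < 5; ++j) sm[j] = pre[j];
        tm_rk4(p, sm, mid);
        if (sm[0] >= 0.0) hi = mid; else lo = mid;
      }
      return t - dt + 0.5 * (lo + hi);
    }
  }
  return NA_REAL;
}

// Euler-Maruyama simulation of the stochastic Traub-Miles system.
// pars[10] = D, pars[11] = sigma2, pars[12] = tau_eta. Gating variables are
// clamped to [0, 1] after each step. Uses R's RNG.
// [[Rcpp::export]]
NumericVector sim_tm_cpp(NumericVector pars, NumericVector state0, double dt,
                         int n_spikes, double max_time, double lockout) {
  TmPars p = tm_unpack(pars);
  const double D = pars[10], sigma2 = pars[11], tau_eta = pars[12];
  RNGScope scope;
  double s[5];
  for (int i = 0; i < 5; ++i) s[i] = state0[i];
  double eta = 0.0, t = 0.0, t_last = -1e9;
  const bool has_ou = sigma2 > 0.0;
  const double sv = std::sqrt(2.0 * D * dt) / p.C;
  const double se = has_ou ? std::sqrt(2.0 * sigma2 * dt / tau_eta) : 0.0;
  NumericVector spikes(n_spikes);
  int got = 0;
  double d[5];
  while (got < n_spikes) {
    if (t > max_time)
      stop("no spike within the time budget (t = %g ms, %d of %d spikes)",
           t, got, n_spikes);
    double V_prev = s[0];
    tm_deriv(p, s, eta, d);
    s[0] += dt * d[0] + sv * ((D > 0.0) ? norm_rand() : 0.0);
    for (int j = 1; j < 5; ++j) {
      s[j] += dt * d[j];
      if (s[j] < 0.0) s[j] = 0.0;
      if (s[j] > 1.0) s[j] = 1.0;
    }
    if (has_ou) eta += -dt * eta / tau_eta + se * norm_rand();
    t += dt;
    if (V_prev < 0.0 && s[0] >= 0.0 && (t - t_last) > lockout) {
      double frac = (0.0 - V_prev) / (s[0] - V_prev);
      double tc = t - dt + frac * dt;
      spikes[got++] = tc;
      t_last = tc;
    }
  }
  return spikes;
}
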