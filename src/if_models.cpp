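// Deterministic integrators and Euler-Maruyama simulator for the
// integrate-and-fire family (LIF, QIF in theta coordinates, GIF) with
// spike-triggered adaptation a(t) and Ornstein-Uhlenbeck colored noise.
//
// Model kinds: 0 = lif, 1 = qif (integrated as theta = 2*atan(v)),
//              2 = gif (one auxiliary variable w).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct IfPars {
  int kind;
  double mu, gamma, beta_w, tau_w;
  double v_threshold, v_reset, w_reset;
  double tau_a;
};

// drift of (x, w); the adaptation current a enters as an explicit function of
// time between spikes, a(t) = a_star * exp(-t/tau_a), which is exact because
// a is purely spike-triggered.
static inline void if_drift(const IfPars &p, double t, double a_star,
                            double x, double w, double &dx, double &dw) {
  const double a = (p.tau_a > 0.0) ? a_star * std::exp(-t / p.tau_a) : 0.0;
  switch (p.kind) {
  case 0: // lif
    dx = -p.gamma * x + p.mu - a;
    dw = 0.0;
    break;
  case 1: // qif in theta coordinates
    dx = (1.0 - std::cos(x)) + (1.0 + std::cos(x)) * (p.mu - a);
    dw = 0.0;
    break;
  default: // gif
    dx = -p.gamma * x - p.beta_w * w + p.mu - a;
    dw = (x - w) / p.tau_w;
    break;
  }
}

static inline void rk4(const IfPars &p, double a_star, double t, double h,
                       double &x, double &w) {
  double k1x, k1w, k2x, k2w, k3x, k3w, k4x, k4w;
  if_drift(p, t, a_star, x, w, k1x, k1w);
  if_drift(p, t + 0.5 * h, a_star, x + 0.5 * h * k1x, w + 0.5 * h * k1w, k2x, k2w);
  if_drift(p, t + 0.5 * h, a_star, x + 0.5 * h * k2x, w + 0.5 * h * k2w, k3x, k3w);
  if_drift(p, t + h, a_star, x + h * k3x, w + h * k3w, k4x, k4w);
  x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
  w += h / 6.0 * (k1w + 2.0 * k2w + 2.0 * k3w + k4w);
}

static IfPars unpack(const List &pars) {
  IfPars p;
  p.kind = as<int>(pars["kind"]);
  p.mu = as<double>(pars["mu"]);
  p.gamma = as<double>(pars["gamma"]);
  p.beta_w = as<double>(pars["beta_w"]);
  p.tau_w = as<double>(pars["tau_w"]);
  p.v_threshold = as<double>(pars["v_threshold"]);
  p.w_reset = as<double>(pars["w_reset"]);
  p.v_reset = as<double>(pars["v_reset"]);
  p.tau_a = as<double>(pars["tau_a"]);
  return p;
}

// Integrate from the reset point with fixed a_star until the threshold
// variable crosses; refine the crossing time by bisection on RK4 substeps.
// Returns NumericVector(time, x_end, w_end); time is NA if no crossing.
// [[Rcpp::export]]
NumericVector if_cross_cpp(List pars, double a_star, double h, double horizon) {
  IfPars p = unpack(pars);
  const double thr = (p.kind == 1) ? M_PI : p.v_threshold;
  double x = (p.kind == 1) ? -M_PI : p.v_reset;
  double w = p.w_reset;
  double t = 0.0;
  const long max_steps = (long)std::ceil(horizon / h) + 1;
  for (long i = 0; i < max_steps; ++i) {
    double x1 = x, w1 = w;
    rk4(p, a_star, t, h, x1, w1);
    if (!std::isfinite(x1)) stop("integration blow-up at t = %g", t);
    if (x1 >= thr && x < thr) {
      // bisection on the substep length s in (0, h]
      double lo = 0.0, hi = h;
      for (int it = 0; it < 80 && (hi - lo) > 1e-15 * std::max(1.0, h); ++it) {
        double mid = 0.5 * (lo + hi);
        double xm = x, wm = w;
        rk4(p, a_star, t, mid, xm, wm);
        if (xm >= thr) hi = mid; else lo = mid;
      }
      double s = 0.5 * (lo + hi);
      double xe = x, we = w;
      rk4(p, a_star, t, s, xe, we);
      return NumericVector::create(t + s, xe, we);
    }
    x = x1; w = w1; t += h;
  }
  return NumericVector::create(NA_REAL, x, w);
}

// Sample the limit-cycle trajectory on a uniform grid of n+1 points over
// [0, period], integrating with one RK4 step per grid interval.
// Returns matrix with columns t, x, w.
// [[Rcpp::export]]
NumericMatrix if_traj_cpp(List pars, double a_star, double period, int n) {
  IfPars p = unpack(pars);
  NumericMatrix out(n + 1, 3);
  double x = (p.kind == 1) ? -M_PI : p.v_reset;
  double w = p.w_reset;
  const double h = period / n;
  out(0, 0) = 0.0; out(0, 1) = x; out(0, 2) = w;
  for (int i = 0; i < n; ++i) {
    rk4(p, a_star, i * h, h, x, w);
    out(i + 1, 0) = (i + 1) * h;
    out(i + 1, 1) = x;
    out(i + 1, 2) = w;
  }
  return out;
}

// Deterministic time-to-threshold from an arbitrary on-cycle state perturbed
// or not; the adaptation current decays from value a0 at local time zero.
// Used by the direct (delta-kick) phase-response estimate.
// [[Rcpp::export]]
double if_cross_from_cpp(List pars, double x0, double w0, double a0,
                         double h, double horizon) {
  IfPars p = unpack(pars);
  const double thr = (p.kind == 1) ? M_PI : p.v_threshold;
  double x = x0, w = w0, t = 0.0;
  const long max_steps = (long)std::ceil(horizon / h) + 1;
  for (long i = 0; i < max_steps; ++i) {
    double x1 = x, w1 = w;
    rk4(p, a0, t, h, x1, w1);
    if (!std::isfinite(x1)) stop("integration blow-up at t = %g", t);
    if (x1 >= thr && x < thr) {
      double lo = 0.0, hi = h;
      for (int it = 0; it < 80; ++it) {
        double mid = 0.5 * (lo + hi);
        double xm = x, wm = w;
        rk4(p, a0, t, mid, xm, wm);
        if (xm >= thr) hi = mid; else lo = mid;
      }
      return t + 0.5 * (lo + hi);
    }
    x = x1; w = w1; t += h;
  }
  return NA_REAL;
}

// Euler-Maruyama simulation of the full stochastic system.
//
// noise_mode: 0 independent white + OU increments, 1 green (the OU and the
// white source share one increment with opposite signs, xi_v = -xi_eta).
// For the QIF, theta_mode = true integrates the theta transform (requires
// d_white = 0, enforced by the caller); otherwise the voltage is integrated
// with numerical bounds +-v_bound and 1/v asymptotic crossing correction.
// Spike times are located by linear interpolation within the crossing step.
// Uses R's RNG (seed with set.seed() before calling).
// [[Rcpp::export]]
NumericVector sim_if_cpp(List pars, double jump, double a0,
                         double d_white, double sigma2, double tau_eta,
                         int noise_mode, double dt, int n_spikes,
                         bool theta_mode, double v_bound, double max_time) {
  IfPars p = unpack(pars);
  RNGScope scope;
  NumericVector spikes(n_spikes);
  const bool qif = (p.kind == 1);
  const bool use_theta = qif && theta_mode;
  const double thr = use_theta ? M_PI : (qif ? v_bound : p.v_threshold);
  const double reset = use_theta ? -M_PI : (qif ? -v_bound : p.v_reset);
  double x = reset, w = p.w_reset, a = a0, eta = 0.0;
  double t = 0.0;
  int got = 0;
  const bool has_ou = sigma2 > 0.0;
  const double sv = std::sqrt(2.0 * d_white * dt);
  const double se = has_ou ? std::sqrt(2.0 * sigma2 * dt / tau_eta) : 0.0;
  long step = 0;
  while (got < n_spikes) {
    if (t > max_time)
      stop("no spike within the time budget (t = %g, %d of %d spikes)", t, got, n_spikes);
    double xi_e = has_ou ? norm_rand() : 0.0;
    double xi_v;
    if (noise_mode == 1) xi_v = -xi_e; else xi_v = (d_white > 0.0) ? norm_rand() : 0.0;

    double dx, dw;
    double x_old = x;
    switch (p.kind) {
    case 0:
      dx = -p.gamma * x + p.mu - a + eta;
      x += dt * dx + sv * xi_v;
      break;
    case 1:
      if (use_theta) {
        dx = (1.0 - std::cos(x)) + (1.0 + std::cos(x)) * (p.mu - a + eta);
        x += dt * dx;
      } else {
        dx = x * x + p.mu - a + eta;
        x += dt * dx + sv * xi_v;
      }
      break;
    default:
      dx = -p.gamma * x - p.beta_w * w + p.mu - a + eta;
      dw = (x - w) / p.tau_w;
      x += dt * dx + sv * xi_v;
      w += dt * dw;
      break;
    }
    if (p.tau_a > 0.0) a -= dt * a / p.tau_a;
    if (has_ou) eta += -dt * eta / tau_eta + se * xi_e;
    t += dt;
    if ((++step & 0xFFFF) == 0 && !std::isfinite(x))
      stop("integration blow-up (NaN state) at step %ld", step);

    if (x >= thr && x_old < thr) {
      double tsp;
      if (qif && !use_theta) {
        // asymptotic correction: remaining time to +infinity is about 1/v
        tsp = t + 1.0 / x;
      } else {
        double frac = (thr - x_old) / (x - x_old);
        tsp = t - dt + frac * dt;
      }
      spikes[got++] = tsp;
      x = reset;
      w = p.w_reset;
      a += jump;
    }
  }
  return spikes;
}
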