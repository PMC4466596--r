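#include <Rcpp.h>
#include "rng.h"
using namespace Rcpp;

// Reduced rule-module right-hand side and the coupled trial simulator.
// Couplings are passed as a fixed-order numeric vector built on the R side:
// [0] JN11 [1] JN12 [2] JA11 [3] JA12 [4] I0 [5] gamma [6] tau_nmda
// Time is in ms throughout; firing rates in Hz (hence the /1000 in the
// gating production term).

static inline double transfer_rate(double x_self, double x_other,
                                   double JAii, double JAij) {
  const double a = 239400.0 * JAii + 270.0;
  const double b = 97000.0 * JAii + 108.0;
  const double d = -30.0 * JAii + 0.154;
  // theta(0) = 0 convention: the cross-population AMPA term switches on
  // strictly above 0.4
  const double fA = (x_other > 0.4) ? JAij * (-276.0 * x_other + 106.0) : 0.0;
  const double u = a * x_self - fA - b;
  if (std::fabs(u) < 1e-9) return 1.0 / d;  // removable singularity
  return u / (1.0 - std::exp(-d * u));
}

struct RuleRHS {
  double JN11, JN12, JA11, JA12, I0, gamma, tau_nmda;
  explicit RuleRHS(const NumericVector &cpl) {
    JN11 = cpl[0]; JN12 = cpl[1]; JA11 = cpl[2]; JA12 = cpl[3];
    I0 = cpl[4]; gamma = cpl[5]; tau_nmda = cpl[6];
  }
  inline void rates(double S1, double S2, double I1, double I2,
                    double &r1, double &r2) const {
    const double x1 = JN11 * S1 - JN12 * S2 + I0 + I1;
    const double x2 = JN11 * S2 - JN12 * S1 + I0 + I2;
    r1 = transfer_rate(x1, x2, JA11, JA12);
    r2 = transfer_rate(x2, x1, JA11, JA12);
  }
  inline void drift(double S1, double S2, double I1, double I2,
                    double &d1, double &d2, double &r1, double &r2) const {
    rates(S1, S2, I1, I2, r1, r2);
    d1 = -S1 / tau_nmda + (1.0 - S1) * gamma * r1 / 1000.0;
    d2 = -S2 / tau_nmda + (1.0 - S2) * gamma * r2 / 1000.0;
  }
};

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// [[Rcpp::export]]
NumericVector cpp_settle_rule(NumericVector cpl, double S1, double S2,
                              double I1, double I2, double dt,
                              double max_ms, double tol) {
  RuleRHS f(cpl);
  double d1, d2, r1, r2, t = 0.0;
  f.drift(S1, S2, I1, I2, d1, d2, r1, r2);
  while (t < max_ms && std::sqrt(d1 * d1 + d2 * d2) >= tol) {
    S1 = clamp01(S1 + dt * d1);
    S2 = clamp01(S2 + dt * d2);
    t += dt;
    f.drift(S1, S2, I1, I2, d1, d2, r1, r2);
  }
  return NumericVector::create(S1, S2, r1, r2, t);
}

// Euler-Maruyama on the gating variables with exactly discretised OU noise.
// I1_vec/I2_vec hold the per-step selective inputs (length n_steps).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_rule(NumericVector cpl, double sigma_rule,
                                double S1, double S2,
                                NumericVector I1_vec, NumericVector I2_vec,
                                double dt, double tau_ou, int seed,
                                int thin) {
  RuleRHS f(cpl);
  Xoshiro rng(static_cast<uint64_t>(seed));
  const int n_steps = I1_vec.size();
  const double e = std::exp(-dt / tau_ou);
  const double sd_ou = sigma_rule / std::sqrt(2.0);   // stationary sd
  const double kick = sd_ou * std::sqrt(1.0 - e * e);
  double n1 = 0.0, n2 = 0.0, d1, d2, r1, r2;
  const int n_rec = n_steps / thin + 1;
  NumericMatrix out(n_rec, 7);
  int k = 0;
  f.rates(S1, S2, I1_vec[0], I2_vec[0], r1, r2);
  out(k, 0) = 0.0; out(k, 1) = S1; out(k, 2) = S2;
  out(k, 3) = r1; out(k, 4) = r2; out(k, 5) = n1; out(k, 6) = n2;
  ++k;
  for (int i = 0; i < n_steps; ++i) {
    f.drift(S1, S2, I1_vec[i], I2_vec[i], d1, d2, r1, r2);
    S1 = clamp01(S1 + dt * (d1 + n1 / 1000.0));
    S2 = clamp01(S2 + dt * (d2 + n2 / 1000.0));
    n1 = n1 * e + kick * rng.rnorm();
    n2 = n2 * e + kick * rng.rnorm();
    if ((i + 1) % thin == 0 && k < n_rec) {
      f.rates(S1, S2,
              i + 1 < n_steps ? I1_vec[i + 1] : 0.0,
              i + 1 < n_steps ? I2_vec[i + 1] : 0.0, r1, r2);
      out(k, 0) = (i + 1) * dt; out(k, 1) = S1; out(k, 2) = S2;
      out(k, 3) = r1; out(k, 4) = r2; out(k, 5) = n1; out(k, 6) = n2;
      ++k;
    }
  }
  return out;
}

// Long free-running simulation accumulated straight into a 2-D occupancy
// histogram over [0,1]^2 (used to cross-check the Fokker-Planck steady
// state without storing the trajectory).
// [[Rcpp::export]]
IntegerMatrix cpp_rule_histogram(NumericVector cpl, double sigma_rule,
                                 double S1, double S2, double n_steps,
                                 double dt, double tau_ou, int seed,
                                 int nbin, double burn_steps) {
  RuleRHS f(cpl);
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double e = std::exp(-dt / tau_ou);
  const double kick = sigma_rule / std::sqrt(2.0) * std::sqrt(1.0 - e * e);
  double n1 = 0.0, n2 = 0.0, d1, d2, r1, r2;
  IntegerMatrix H(nbin, nbin);
  const long long N = static_cast<long long>(n_steps);
  const long long B = static_cast<long long>(burn_steps);
  for (long long i = 0; i < N; ++i) {
    f.drift(S1, S2, 0.0, 0.0, d1, d2, r1, r2);
    S1 = clamp01(S1 + dt * (d1 + n1 / 1000.0));
    S2 = clamp01(S2 + dt * (d2 + n2 / 1000.0));
    n1 = n1 * e + kick * rng.rnorm();
    n2 = n2 * e + kick * rng.rnorm();
    if (i >= B) {
      int ix = static_cast<int>(S1 * nbin); if (ix == nbin) ix = nbin - 1;
      int iy = static_cast<int>(S2 * nbin); if (iy == nbin) iy = nbin - 1;
      H(ix, iy) += 1;
    }
  }
  return H;
}

// Plain OU process sample path (diagnostics: stationary variance checks).
// [[Rcpp::export]]
NumericVector cpp_ou_path(double sigma, double tau_ou, int n_steps,
                          double dt, int seed) {
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double e = std::exp(-dt / tau_ou);
  const double kick = sigma / std::sqrt(2.0) * std::sqrt(1.0 - e * e);
  NumericVector out(n_steps);
  double x = 0.0;
  for (int i = 0; i < n_steps; ++i) {
    x = x * e + kick * rng.rnorm();
    out[i] = x;
  }
  return out;
}

struct DecisionStep {
  double alpha, beta, tau;
  // one Euler step of the reduced three-dimensional decision dynamics
  inline void step(double &X, double &Y, double &Z,
                   double dI1, double dI2, double dI3, double dI4,
                   double nX, double nY, double nZ, double dt) const {
    const double dX = (alpha * 0.5 * (dI1 - dI2) + beta * X * Z + nX) / tau;
    const double dY = (alpha * 0.5 * (dI3 - dI4) - beta * Y * Z + nY) / tau;
    const double dZ = (alpha * 0.25 * (dI1 + dI2 - dI3 - dI4) +
                       beta * 0.25 * (X * X - Y * Y) + nZ) / tau;
    X += dt * dX; Y += dt * dY; Z += dt * dZ;
  }
};

static inline void project4(double X, double Y, double Z, double *p) {
  p[0] = 0.5 * X + 0.5 * Z;
  p[1] = -0.5 * X + 0.5 * Z;
  p[2] = 0.5 * Y - 0.5 * Z;
  p[3] = -0.5 * Y - 0.5 * Z;
}

// first projection to cross `threshold` wins; simultaneous crossings are
// resolved in favour of the larger projection, exact ties by pool order
static inline int winner(const double *p, double threshold) {
  int best = 0; double bestv = -1e300;
  for (int j = 0; j < 4; ++j) {
    if (p[j] >= threshold && p[j] > bestv) { best = j + 1; bestv = p[j]; }
  }
  return bestv >= threshold ? best : 0;
}

// Decision module driven by an externally supplied rule-rate series
// (r1_vec, r2_vec sampled at dt, covering at least the stimulus window).
// [[Rcpp::export]]
List cpp_simulate_decision(double alpha, double beta, double sigma_dec,
                           double threshold, double tau,
                           NumericVector D, double c_plus,
                           NumericVector r1_vec, NumericVector r2_vec,
                           double stim_ms, double trial_ms, double dt,
                           double tau_ou, int seed, bool record) {
  DecisionStep g; g.alpha = alpha; g.beta = beta; g.tau = tau;
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double e = std::exp(-dt / tau_ou);
  const double kick = sigma_dec / std::sqrt(2.0) * std::sqrt(1.0 - e * e);
  const int n_steps = static_cast<int>(trial_ms / dt + 0.5);
  const int n_stim = static_cast<int>(stim_ms / dt + 0.5);
  double X = 0, Y = 0, Z = 0, nX = 0, nY = 0, nZ = 0;
  double p[4];
  int decision = 0;
  double rt = NA_REAL;
  int n_rec = 1;
  NumericMatrix traj;
  if (record) traj = NumericMatrix(n_steps + 1, 8);
  if (record) {
    project4(X, Y, Z, p);
    traj(0, 0) = 0; traj(0, 1) = X; traj(0, 2) = Y; traj(0, 3) = Z;
    for (int j = 0; j < 4; ++j) traj(0, 4 + j) = p[j];
  }
  for (int i = 0; i < n_steps; ++i) {
    double dI1 = 0, dI2 = 0, dI3 = 0, dI4 = 0;
    if (i < n_stim) {
      const double r1 = r1_vec[i], r2 = r2_vec[i];
      dI1 = D[0] + c_plus * r1;
      dI2 = D[1] + c_plus * r1;
      dI3 = D[2] + c_plus * r2;
      dI4 = D[3] + c_plus * r2;
    }
    g.step(X, Y, Z, dI1, dI2, dI3, dI4, nX, nY, nZ, dt);
    nX = nX * e + kick * rng.rnorm();
    nY = nY * e + kick * rng.rnorm();
    nZ = nZ * e + kick * rng.rnorm();
    project4(X, Y, Z, p);
    if (record) {
      traj(i + 1, 0) = (i + 1) * dt;
      traj(i + 1, 1) = X; traj(i + 1, 2) = Y; traj(i + 1, 3) = Z;
      for (int j = 0; j < 4; ++j) traj(i + 1, 4 + j) = p[j];
    }
    if (decision == 0) {
      const int w = winner(p, threshold);
      if (w > 0) {
        decision = w;
        rt = (i + 1) * dt;
        n_rec = i + 2;
        break;   // divergence past threshold is suppressed
      }
    }
    n_rec = i + 2;
  }
  if (record) {
    // truncate at the crossing step
    NumericMatrix out(n_rec, 8);
    for (int r = 0; r < n_rec; ++r)
      for (int c = 0; c < 8; ++c) out(r, c) = traj(r, c);
    return List::create(_["decision"] = decision, _["rt"] = rt,
                        _["trajectory"] = out);
  }
  return List::create(_["decision"] = decision, _["rt"] = rt);
}

// Full coupled trial batch: rule module (from a pre-settled initial state)
// plus decision module, both with OU noise. Returns one row per trial:
// decision (0 = none), rt in ms, and the spike-rate integral
// \int (r1 + r2) dt over the whole trial (NA unless record_energy).
// [[Rcpp::export]]
NumericMatrix cpp_simulate_trials(NumericVector cpl, double sigma_rule,
                                  double S1_init, double S2_init,
                                  double I1, double I2,
                                  NumericVector D, double c_plus,
                                  double alpha, double beta,
                                  double sigma_dec, double threshold,
                                  double tau_dec,
                                  int n_trials, double stim_ms,
                                  double trial_ms, double dt,
                                  double tau_ou, int seed,
                                  bool record_energy) {
  RuleRHS f(cpl);
  DecisionStep g; g.alpha = alpha; g.beta = beta; g.tau = tau_dec;
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double e = std::exp(-dt / tau_ou);
  const double kick_r = sigma_rule / std::sqrt(2.0) * std::sqrt(1.0 - e * e);
  const double kick_d = sigma_dec / std::sqrt(2.0) * std::sqrt(1.0 - e * e);
  const int n_steps = static_cast<int>(trial_ms / dt + 0.5);
  const int n_stim = static_cast<int>(stim_ms / dt + 0.5);
  NumericMatrix out(n_trials, 3);
  double p[4];
  for (int tr = 0; tr < n_trials; ++tr) {
    double S1 = S1_init, S2 = S2_init, n1 = 0, n2 = 0;
    double X = 0, Y = 0, Z = 0, nX = 0, nY = 0, nZ = 0;
    double d1, d2, r1, r2, energy = 0.0;
    int decision = 0;
    double rt = NA_REAL;
    for (int i = 0; i < n_steps; ++i) {
      const bool stim_on = i < n_stim;
      f.drift(S1, S2, stim_on ? I1 : 0.0, stim_on ? I2 : 0.0,
              d1, d2, r1, r2);
      if (record_energy) energy += (r1 + r2) * dt;
      if (decision == 0) {
        double dI1 = 0, dI2 = 0, dI3 = 0, dI4 = 0;
        if (stim_on) {
          dI1 = D[0] + c_plus * r1;
          dI2 = D[1] + c_plus * r1;
          dI3 = D[2] + c_plus * r2;
          dI4 = D[3] + c_plus * r2;
        }
        g.step(X, Y, Z, dI1, dI2, dI3, dI4, nX, nY, nZ, dt);
        nX = nX * e + kick_d * rng.rnorm();
        nY = nY * e + kick_d * rng.rnorm();
        nZ = nZ * e + kick_d * rng.rnorm();
        project4(X, Y, Z, p);
        const int w = winner(p, threshold);
        if (w > 0) { decision = w; rt = (i + 1) * dt; }
      }
      S1 = clamp01(S1 + dt * (d1 + n1 / 1000.0));
      S2 = clamp01(S2 + dt * (d2 + n2 / 1000.0));
      n1 = n1 * e + kick_r * rng.rnorm();
      n2 = n2 * e + kick_r * rng.rnorm();
      if (!record_energy && decision != 0) break;
    }
    out(tr, 0) = decision;
    out(tr, 1) = rt;
    out(tr, 2) = record_energy ? energy : NA_REAL;
  }
  return out;
}

// Direct Euler-Maruyama simulation of the white-noise (small-noise limit)
// form of the rule-module SDE, dS/dt = F(S) + sqrt(2 D) xi(t) with time in
// seconds and D = (sigma_rule/2)^2, as an ensemble of independent walkers
// started uniformly on the unit square; occupancy is accumulated into an
// nbin x nbin histogram after a per-walker burn-in.
// [[Rcpp::export]]
NumericMatrix cpp_eq9_histogram(NumericVector cpl, double sigma_rule,
                                int n_walkers, double n_steps,
                                double burn_steps, double dt_s, int seed,
                                int nbin) {
  RuleRHS f(cpl);
  Xoshiro rng(static_cast<uint64_t>(seed));
  const double Dd = (sigma_rule / 2.0) * (sigma_rule / 2.0);
  const double kick = std::sqrt(2.0 * Dd * dt_s);
  NumericMatrix H(nbin, nbin);
  const long long N = static_cast<long long>(n_steps);
  const long long B = static_cast<long long>(burn_steps);
  double d1, d2, r1, r2;
  for (int w = 0; w < n_walkers; ++w) {
    double S1 = rng.runif();
    double S2 = rng.runif();
    for (long long i = 0; i < N; ++i) {
      f.drift(S1, S2, 0.0, 0.0, d1, d2, r1, r2);
      // drift is per ms; the SDE runs in seconds
      S1 = clamp01(S1 + dt_s * d1 * 1000.0 + kick * rng.rnorm());
      S2 = clamp01(S2 + dt_s * d2 * 1000.0 + kick * rng.rnorm());
      if (i >= B) {
        int ix = static_cast<int>(S1 * nbin); if (ix == nbin) ix = nbin - 1;
        int iy = static_cast<int>(S2 * nbin); if (iy == nbin) iy = nbin - 1;
        H(ix, iy) += 1.0;
      }
    }
  }
  return H;
}
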