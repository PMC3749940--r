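#ifndef BVRSIM_MARKOV_CORE_H
#define BVRSIM_MARKOV_CORE_H

#include <vector>
#include <cmath>
#include <algorithm>
#include <stdexcept>
#include "rng.h"

// Core state-transition kernels shared by the generic gating engine and the
// myocyte model. Rate matrices Q are row-major with Q[i*n + j] the transition
// rate (1/ms) from state i to state j; diagonal entries are ignored.
//
// All kernels sub-step adaptively so that no *occupied* state's exit
// probability sum exceeds MAX_EXIT_PROB per sub-step; empty states cannot
// move probability mass, so stiff rates out of unoccupied states do not
// force small sub-steps.

namespace bvr {

constexpr double MAX_EXIT_PROB = 0.1;
constexpr double OCC_EPS = 1e-9;

inline void check_rates(const double *Q, int n) {
  for (int i = 0; i < n * n; ++i)
    if (Q[i] < 0.0 || !std::isfinite(Q[i]))
      throw std::runtime_error("negative or non-finite transition rate in Markov scheme");
}

// Worst per-state exit rate among states that actually hold probability
// mass. `rel` additionally excludes states holding less than that fraction
// of the total: their (few) channels are moved with clamped probabilities
// toward the rate-weighted dominant destination instead of forcing tiny
// sub-steps on the whole scheme.
inline double worst_exit(const double *occ, const double *Q, int n,
                         double thresh, double rel = 0.0) {
  double total = 0.0;
  if (rel > 0.0) for (int i = 0; i < n; ++i) total += occ[i];
  double cut = thresh;
  if (rel > 0.0 && rel * total > cut) cut = rel * total;
  double worst = 0.0;
  for (int i = 0; i < n; ++i) {
    if (occ[i] < cut) continue;
    double tot = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) tot += Q[i * n + j];
    if (tot > worst) worst = tot;
  }
  return worst;
}

// Stochastic multinomial update of integer occupancies (stored as doubles).
// Per sub-step, the number of channels leaving state i is binomial with the
// exact single-channel departure probability 1 - exp(-r_tot h) (so the
// update is stable for arbitrarily stiff schemes), distributed over the
// destinations proportionally to their rates via sequential conditional
// binomials (a multinomial draw). The expectation of one step equals the
// deterministic update to O(h^2). Sub-stepping keeps exit probabilities
// near MAX_EXIT_PROB where affordable (bounded by MAX_SUBSTEPS).
constexpr int MAX_SUBSTEPS = 4;

inline void markov_step_stoch(double *occ, const double *Q, int n, double dt,
                              RngEngine &rng) {
  if (dt <= 0.0) return;
  check_rates(Q, n);
  std::vector<double> delta(n);
  double w = worst_exit(occ, Q, n, 0.5);
  int nsub = (w * dt <= MAX_EXIT_PROB)
                 ? 1
                 : (int)std::ceil(w * dt / MAX_EXIT_PROB);
  if (nsub > MAX_SUBSTEPS) nsub = MAX_SUBSTEPS;
  double h = dt / nsub;
  for (int s = 0; s < nsub; ++s) {
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      long ni = (long)std::llround(occ[i]);
      if (ni <= 0) continue;
      double rtot = 0.0;
      for (int j = 0; j < n; ++j) if (j != i) rtot += Q[i * n + j];
      if (rtot <= 0.0) continue;
      double p_leave = 1.0 - std::exp(-rtot * h);
      long movers = rng.binom(ni, p_leave);
      delta[i] -= (double)movers;
      // split movers over destinations ~ Multinomial(r_ij / r_tot)
      double rrem = rtot;
      for (int j = 0; j < n && movers > 0; ++j) {
        if (j == i) continue;
        double r = Q[i * n + j];
        if (r <= 0.0) continue;
        long m;
        if (r >= rrem) m = movers;
        else m = rng.binom(movers, r / rrem);
        delta[j] += (double)m;
        movers -= m;
        rrem -= r;
      }
    }
    for (int i = 0; i < n; ++i) occ[i] += delta[i];
  }
}

// Deterministic update of state fractions by exponential departures: each
// state loses frac_i * (1 - exp(-r_tot * dt)), distributed over destinations
// proportionally to their rates. Agrees with forward Euler to O(dt^2),
// is unconditionally stable for stiff schemes, and preserves the sum exactly.
inline void markov_det_pass(double *frac, const double *Q, int n, double dt) {
  std::vector<double> delta(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = frac[i];
    if (xi <= 0.0) continue;
    double rtot = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) rtot += Q[i * n + j];
    if (rtot <= 0.0) continue;
    double leave = xi * (1.0 - std::exp(-rtot * dt));
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double f = leave * Q[i * n + j] / rtot;
      delta[i] -= f;
      delta[j] += f;
    }
  }
  for (int i = 0; i < n; ++i) {
    frac[i] += delta[i];
    if (frac[i] < 0.0) frac[i] = 0.0;
    if (frac[i] > 1.0) frac[i] = 1.0;
  }
}

inline void markov_step_det(double *frac, const double *Q, int n, double dt) {
  if (dt <= 0.0) return;
  check_rates(Q, n);
  if (n == 2) {
    // exact two-state relaxation toward a/(a+b)
    double a = Q[1], b = Q[2];
    double s = a + b;
    if (s <= 0.0) return;
    double total = frac[0] + frac[1];
    double xinf = a / s;
    double p = frac[1] / (total > 0.0 ? total : 1.0);
    double pn = xinf + (p - xinf) * std::exp(-s * dt);
    frac[1] = pn * total;
    frac[0] = total - frac[1];
    return;
  }
  // two half-passes halve the per-step coupling error of the exponential
  // departures while remaining unconditionally stable
  markov_det_pass(frac, Q, n, dt / 2.0);
  markov_det_pass(frac, Q, n, dt / 2.0);
}

// Chemical-Langevin update of state fractions for a population of size N:
// each reaction channel contributes drift r*x*dt and diffusion
// sqrt(r*x*dt/N) * xi, antisymmetrically between source and destination.
inline void markov_step_cle(double *frac, const double *Q, int n, double dt,
                            double N, RngEngine &rng) {
  if (dt <= 0.0) return;
  check_rates(Q, n);
  std::vector<double> delta(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = frac[i];
    if (xi <= 0.0) continue;
    double rtot = 0.0;
    for (int j = 0; j < n; ++j) if (j != i) rtot += Q[i * n + j];
    if (rtot <= 0.0) continue;
    double leave = xi * (1.0 - std::exp(-rtot * dt));   // stable drift
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double f = leave * Q[i * n + j] / rtot;
      // the Langevin diffusion term is valid only when many reaction events
      // occur per step (f*N >> 1); rare transitions advance by drift alone,
      // since boundary clamping of their noise would otherwise bias rare
      // conducting states upward and can latch the action-potential plateau
      bool noisy = (N >= 1.0) && (f * N >= 10.0);
      double noise = noisy ? std::sqrt(f / N) * rng.norm() : 0.0;
      double move = f + noise;
      delta[i] -= move;
      delta[j] += move;
    }
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) {
    frac[i] += delta[i];
    if (frac[i] < 0.0) frac[i] = 0.0;
    tot += frac[i];
  }
  if (tot > 0.0) for (int i = 0; i < n; ++i) frac[i] /= tot;
}

// Langevin update of a single Hodgkin-Huxley gating variable:
// x' = x + [a(1-x) - b x] dt + sqrt([a(1-x) + b x] dt / N) xi, clipped to [0,1].
inline double hh_sde_step(double x, double a, double b, double n_eff,
                          double dt, RngEngine &rng) {
  double drift = a * (1.0 - x) - b * x;
  double diff2 = (a * (1.0 - x) + b * x) * dt / n_eff;
  double xn = x + drift * dt + (diff2 > 0.0 ? std::sqrt(diff2) * rng.norm() : 0.0);
  if (xn < 0.0) xn = 0.0;
  if (xn > 1.0) xn = 1.0;
  return xn;
}

// Two-state (closed/open) binomial channel-count update; returns new open count.
inline double hh_binom_step(double open, double N, double a, double b,
                            double dt, RngEngine &rng) {
  if (dt <= 0.0) return open;
  double worst = (a > b ? a : b) * dt;
  int nsub = worst <= MAX_EXIT_PROB ? 1 : (int)std::ceil(worst / MAX_EXIT_PROB);
  double h = dt / nsub;
  long o = (long)std::llround(open);
  long n = (long)std::llround(N);
  for (int s = 0; s < nsub; ++s) {
    long opened = rng.binom(n - o, a * h);
    long closed = rng.binom(o, b * h);
    o += opened - closed;
    if (o < 0) o = 0;
    if (o > n) o = n;
  }
  return (double)o;
}

// Stationary distribution of a scheme at fixed rates: solves pi Q = 0 with
// sum(pi) = 1 by Gaussian elimination on the (n x n) system.
inline std::vector<double> stationary_dist(const double *Q, int n) {
  std::vector<double> A(n * n, 0.0), b(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      A[j * n + i] += Q[i * n + j];   // inflow to j from i
      tot += Q[i * n + j];
    }
    A[i * n + i] -= tot;              // outflow from i
  }
  for (int j = 0; j < n; ++j) A[(n - 1) * n + j] = 1.0;
  b[n - 1] = 1.0;
  for (int c = 0; c < n; ++c) {
    int best = c;
    for (int r = c + 1; r < n; ++r)
      if (std::fabs(A[r * n + c]) > std::fabs(A[best * n + c])) best = r;
    if (best != c) {
      for (int k = 0; k < n; ++k) std::swap(A[c * n + k], A[best * n + k]);
      std::swap(b[c], b[best]);
    }
    double d = A[c * n + c];
    if (std::fabs(d) < 1e-14) throw std::runtime_error("singular rate matrix in stationary_dist");
    for (int r = c + 1; r < n; ++r) {
      double f = A[r * n + c] / d;
      if (f == 0.0) continue;
      for (int k = c; k < n; ++k) A[r * n + k] -= f * A[c * n + k];
      b[r] -= f * b[c];
    }
  }
  std::vector<double> x(n);
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int k = r + 1; k < n; ++k) s -= A[r * n + k] * x[k];
    x[r] = s / A[r * n + r];
  }
  for (int i = 0; i < n; ++i) if (x[i] < 0.0) x[i] = 0.0;
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += x[i];
  for (int i = 0; i < n; ++i) x[i] /= tot;
  return x;
}

}  // namespace bvr

#endif
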