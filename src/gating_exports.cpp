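#include <Rcpp.h>
#include "markov_core.h"
using namespace Rcpp;

// R matrices are column-major; the kernels expect row-major Q[i*n+j]
static std::vector<double> row_major(const NumericMatrix &Q) {
  int n = Q.nrow();
  std::vector<double> q((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) q[(size_t)i * n + j] = Q(i, j);
  return q;
}

// Persistent RNG stream for the gating engine, so repeated kernel calls from
// R continue one reproducible stream.

// [[Rcpp::export]]
SEXP cpp_rng_create(int seed) {
  XPtr<RngEngine> p(new RngEngine((std::uint64_t)seed), true);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_markov_step_stoch(NumericVector occupancy, NumericMatrix Q,
                                    double dt, SEXP rng) {
  XPtr<RngEngine> p(rng);
  int n = occupancy.size();
  if (Q.nrow() != n || Q.ncol() != n) stop("rate matrix does not match state count");
  std::vector<double> occ(occupancy.begin(), occupancy.end());
  std::vector<double> q = row_major(Q);
  try {
    bvr::markov_step_stoch(occ.data(), q.data(), n, dt, *p);
  } catch (const std::exception &e) {
    stop("%s", e.what());
  }
  return NumericVector(occ.begin(), occ.end());
}

// [[Rcpp::export]]
NumericVector cpp_markov_step_det(NumericVector fractions, NumericMatrix Q,
                                  double dt) {
  int n = fractions.size();
  if (Q.nrow() != n || Q.ncol() != n) stop("rate matrix does not match state count");
  std::vector<double> frac(fractions.begin(), fractions.end());
  std::vector<double> q = row_major(Q);
  try {
    bvr::markov_step_det(frac.data(), q.data(), n, dt);
  } catch (const std::exception &e) {
    stop("%s", e.what());
  }
  return NumericVector(frac.begin(), frac.end());
}

// [[Rcpp::export]]
NumericVector cpp_markov_step_cle(NumericVector fractions, NumericMatrix Q,
                                  double dt, double n_channels, SEXP rng) {
  XPtr<RngEngine> p(rng);
  int n = fractions.size();
  if (Q.nrow() != n || Q.ncol() != n) stop("rate matrix does not match state count");
  std::vector<double> frac(fractions.begin(), fractions.end());
  std::vector<double> q = row_major(Q);
  try {
    bvr::markov_step_cle(frac.data(), q.data(), n, dt, n_channels, *p);
  } catch (const std::exception &e) {
    stop("%s", e.what());
  }
  return NumericVector(frac.begin(), frac.end());
}

// [[Rcpp::export]]
double cpp_hh_sde_step(double x, double alpha, double beta, double n_eff,
                       double dt, SEXP rng) {
  XPtr<RngEngine> p(rng);
  return bvr::hh_sde_step(x, alpha, beta, n_eff, dt, *p);
}

// [[Rcpp::export]]
double cpp_hh_binom_step(double open, double n_channels, double alpha,
                         double beta, double dt, SEXP rng) {
  XPtr<RngEngine> p(rng);
  return bvr::hh_binom_step(open, n_channels, alpha, beta, dt, *p);
}

// [[Rcpp::export]]
NumericVector cpp_stationary_dist(NumericMatrix Q) {
  int n = Q.nrow();
  std::vector<double> q = row_major(Q);
  try {
    std::vector<double> pi = bvr::stationary_dist(q.data(), n);
    return NumericVector(pi.begin(), pi.end());
  } catch (const std::exception &e) {
    stop("%s", e.what());
  }
}
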