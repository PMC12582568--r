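#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Self-consistent solver for the multi-ensemble reweighting (TRAM)
// equations.  All quantities live in log space so that bias energies and
// free-energy differences of tens of kT are handled without overflow.
//
// Unknowns: f(i,k) local reduced free energy of state i in ensemble k,
//           log_v(i,k) log Lagrangian multiplier.
// Inputs:   ct[k]  = c_ij^k + c_ji^k (symmetrized transition counts),
//           colsum[k](i) = sum_j c_ji^k (incoming counts),
//           N(i,k) number of frames of ensemble k assigned to state i,
//           bias(x,k) reduced bias energy frame x would feel in ensemble k,
//           state(x) 0-based state index of frame x.
//
// Per sweep: multiplicative update of v from the flux-balance equation,
// recomputation of the R aggregates, then the f update from the local
// equilibrium condition, followed by a global shift of f that keeps the
// per-frame stationary weights normalized.  Convergence is measured as the
// max absolute change of f over a sweep.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// [[Rcpp::export]]
List tram_solve_cpp(List ct_list, List colsum_list, NumericMatrix N,
                    NumericMatrix bias, IntegerVector state,
                    double tol, int max_iter, int history_stride) {
  const int n = N.nrow();
  const int K = N.ncol();
  const int nx = state.size();

  std::vector<NumericMatrix> ct(K);
  std::vector<NumericVector> colsum(K);
  for (int k = 0; k < K; ++k) {
    ct[k] = as<NumericMatrix>(ct_list[k]);
    colsum[k] = as<NumericVector>(colsum_list[k]);
  }

  // initialization: f from state occupation counts, v from count totals
  NumericMatrix f(n, K), fnew(n, K), log_v(n, K), log_R(n, K);
  std::vector<double> Ntot(K, 0.0);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) Ntot[k] += N(i, k);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) {
      f(i, k) = (N(i, k) > 0) ? -std::log(N(i, k) / Ntot[k]) : 0.0;
      double rs = 0.0;
      for (int j = 0; j < n; ++j) rs += ct[k](i, j);
      log_v(i, k) = (rs > 0) ? std::log(rs / 2.0) : NEG_INF;
    }

  std::vector<double> D(nx);
  std::vector<double> increments;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // --- v update (flux balance) ---
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        if (log_v(i, k) == NEG_INF) continue;
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
          double c = ct[k](i, j);
          if (c == 0.0) continue;
          double den = lse2(f(j, k) - f(i, k) + log_v(j, k), log_v(i, k));
          s += c * std::exp(-den);
        }
        if (s > 0) log_v(i, k) += std::log(s);
      }
    }

    // --- R aggregates ---
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int j = 0; j < n; ++j) {
          double c = ct[k](i, j);
          if (c == 0.0 || log_v(j, k) == NEG_INF) continue;
          double den = lse2(log_v(j, k), f(i, k) - f(j, k) + log_v(i, k));
          s += c * std::exp(log_v(j, k) - den);
        }
        double r = s + N(i, k) - colsum[k][i];
        log_R(i, k) = (r > 1e-300) ? std::log(r) : NEG_INF;
      }
    }

    // --- per-frame log normalizers D(x) = lse_l [log R + f - b] ---
    for (int x = 0; x < nx; ++x) {
      const int i = state[x];
      double m = NEG_INF;
      for (int k = 0; k < K; ++k) {
        if (log_R(i, k) == NEG_INF) continue;
        double t = log_R(i, k) + f(i, k) - bias(x, k);
        if (t > m) m = t;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        if (log_R(i, k) == NEG_INF) continue;
        s += std::exp(log_R(i, k) + f(i, k) - bias(x, k) - m);
      }
      D[x] = m + std::log(s);
    }

    // --- f update (local equilibrium) ---
    // f(i,k) = -log sum_{x in X_i} exp(-bias(x,k) - D(x))
    std::vector<double> acc(n * K, 0.0);
    for (int x = 0; x < nx; ++x) {
      const int i = state[x];
      for (int k = 0; k < K; ++k)
        acc[i * K + k] += std::exp(-bias(x, k) - D[x]);
    }
    // normalization shift keeping sum_x mu(x) = 1
    double m = NEG_INF;
    for (int x = 0; x < nx; ++x) if (-D[x] > m) m = -D[x];
    double sm = 0.0;
    for (int x = 0; x < nx; ++x) sm += std::exp(-D[x] - m);
    const double shift = m + std::log(sm);

    double inc = 0.0;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < K; ++k) {
        double a = acc[i * K + k];
        fnew(i, k) = (a > 0) ? (-std::log(a) + shift) : f(i, k) + shift;
        double d = std::fabs(fnew(i, k) - f(i, k));
        if (std::isfinite(d) && d > inc) inc = d;
      }
    std::swap(f, fnew);
    if (iter % history_stride == 0 || inc < tol) increments.push_back(inc);
    if (inc < tol) { converged = true; break; }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }
  if (iter > max_iter) iter = max_iter;

  // --- final D and per-frame stationary weights ---
  for (int x = 0; x < nx; ++x) {
    const int i = state[x];
    double mm = NEG_INF;
    for (int k = 0; k < K; ++k) {
      if (log_R(i, k) == NEG_INF) continue;
      double t = log_R(i, k) + f(i, k) - bias(x, k);
      if (t > mm) mm = t;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      if (log_R(i, k) == NEG_INF) continue;
      s += std::exp(log_R(i, k) + f(i, k) - bias(x, k) - mm);
    }
    D[x] = mm + std::log(s);
  }
  double mmu = NEG_INF;
  for (int x = 0; x < nx; ++x) if (-D[x] > mmu) mmu = -D[x];
  double smu = 0.0;
  for (int x = 0; x < nx; ++x) smu += std::exp(-D[x] - mmu);
  const double log_z = mmu + std::log(smu);
  NumericVector log_mu(nx);
  for (int x = 0; x < nx; ++x) log_mu[x] = -D[x] - log_z;

  // --- per-ensemble transition matrices (detailed-balance form) ---
  List p_list(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix p(n, n);
    for (int i = 0; i < n; ++i) {
      if (log_v(i, k) == NEG_INF) { p(i, i) = 1.0; continue; }
      double rs = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double c = ct[k](i, j);
        if (c == 0.0 || log_v(j, k) == NEG_INF) continue;
        double den = lse2(f(j, k) - f(i, k) + log_v(j, k), log_v(i, k));
        p(i, j) = c * std::exp(-den);
        rs += p(i, j);
      }
      if (rs > 1.0) { // numerical guard: renormalize the off-diagonal row
        for (int j = 0; j < n; ++j) if (j != i) p(i, j) /= rs;
        rs = 1.0;
      }
      p(i, i) = 1.0 - rs;
    }
    p_list[k] = p;
  }

  return List::create(
      _["f"] = f, _["log_v"] = log_v, _["log_R"] = log_R,
      _["log_mu"] = log_mu, _["transition_matrices"] = p_list,
      _["increments"] = NumericVector(increments.begin(), increments.end()),
      _["converged"] = converged, _["iterations"] = std::min(iter, max_iter));
}
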