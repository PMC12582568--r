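#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gradients of the built-in model potentials and biases, kept in C++ so the
// integrator loop never calls back into R.
//   pot_code: 1 = double well h(x^2-1)^2 + tilt*x   (par = {h, tilt})
//             2 = harmonic kappa/2 (x-x0)^2          (par = {kappa, x0})
//             0 = flat
static inline double pot_grad(int code, const double *par, double x) {
  switch (code) {
  case 1: return 4.0 * par[0] * x * (x * x - 1.0) + par[1];
  case 2: return par[0] * (x - par[1]);
  default: return 0.0;
  }
}

static inline double pot_energy(int code, const double *par, double x) {
  switch (code) {
  case 1: { double d = x * x - 1.0; return par[0] * d * d + par[1] * x; }
  case 2: { double d = x - par[1]; return 0.5 * par[0] * d * d; }
  default: return 0.0;
  }
}

// Overdamped (Brownian) Euler-Maruyama integrator:
//   x <- x - beta * D * grad(U + bias) * dt + sqrt(2 D dt) * eta
// Columns of the returned matrix are independent replicas started from x0.
// bias_code: 0 none, 1 harmonic umbrella (bias_par = {k, center}, energy in
// kT: k/2 (x-c)^2).
// [[Rcpp::export]]
NumericMatrix langevin_cpp(NumericVector x0, int n_steps, double dt,
                           double diffusion, double beta, int stride,
                           int pot_code, NumericVector pot_par,
                           int bias_code, NumericVector bias_par,
                           double domain_guard) {
  const int n_rep = x0.size();
  const int n_frames = n_steps / stride;
  NumericMatrix out(n_frames, n_rep);
  const double pref = beta * diffusion * dt;
  const double noise = std::sqrt(2.0 * diffusion * dt);
  const double *pp = REAL(pot_par);
  const double *bp = REAL(bias_par);
  RNGScope scope;
  for (int r = 0; r < n_rep; ++r) {
    double x = x0[r];
    int fi = 0;
    for (int s = 1; s <= n_steps; ++s) {
      double g = pot_grad(pot_code, pp, x);
      if (bias_code == 1) g += bp[0] * (x - bp[1]);
      x += -pref * g + noise * norm_rand();
      if (std::fabs(x) > domain_guard || !std::isfinite(x))
        stop("trajectory diverged at step %d (x = %g); reduce the timestep",
             s, x);
      if (s % stride == 0) out(fi++, r) = x;
    }
  }
  return out;
}

// Well-tempered metadynamics on a 1-D potential.  The accumulated bias and
// its derivative are kept on a uniform grid (updated analytically at each
// deposition) and linearly interpolated inside the integrator, so the cost
// per step is O(1) in the number of hills.
// Hill height follows the well-tempered schedule
//   W(t) = w0 * exp(-V_meta(x, t) / (kB * dT))
// with energies in kT, so kB*dT = dT / T in these units.
// [[Rcpp::export]]
List wtmetad_cpp(double x0, int n_steps, double dt, double diffusion,
                 double beta, int stride, int pot_code, NumericVector pot_par,
                 double w0, double sigma, double dT_over_T,
                 int hill_stride, double grid_min, double grid_max,
                 int n_grid, double domain_guard) {
  const int n_frames = n_steps / stride;
  const int n_hills_max = (hill_stride > 0) ? n_steps / hill_stride : 0;
  NumericVector traj(n_frames);
  NumericVector hill_time(n_hills_max), hill_center(n_hills_max),
      hill_height(n_hills_max);
  NumericVector vgrid(n_grid), fgrid(n_grid); // bias energy and d(bias)/dx
  const double dx = (grid_max - grid_min) / (n_grid - 1);
  const double pref = beta * diffusion * dt;
  const double noise = std::sqrt(2.0 * diffusion * dt);
  const double *pp = REAL(pot_par);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  RNGScope scope;
  double x = x0;
  int fi = 0, nh = 0;
  auto interp = [&](const NumericVector &g, double p) {
    if (p <= grid_min) return g[0];
    if (p >= grid_max) return g[n_grid - 1];
    double u = (p - grid_min) / dx;
    int i = (int)u;
    double w = u - i;
    return (1.0 - w) * g[i] + w * g[i + 1];
  };
  for (int s = 1; s <= n_steps; ++s) {
    double g = pot_grad(pot_code, pp, x) + interp(fgrid, x);
    x += -pref * g + noise * norm_rand();
    if (std::fabs(x) > domain_guard || !std::isfinite(x))
      stop("metadynamics trajectory diverged at step %d (x = %g)", s, x);
    if (hill_stride > 0 && s % hill_stride == 0) {
      double vcur = interp(vgrid, x);
      double W = (dT_over_T > 0) ? w0 * std::exp(-vcur / dT_over_T) : w0;
      hill_time[nh] = s * dt;
      hill_center[nh] = x;
      hill_height[nh] = W;
      ++nh;
      if (W > 0) {
        for (int i = 0; i < n_grid; ++i) {
          double d = grid_min + i * dx - x;
          double e = W * std::exp(-d * d * inv2s2);
          vgrid[i] += e;
          fgrid[i] += -d * 2.0 * inv2s2 * e; // d/dg of the deposited Gaussian
        }
      }
    }
    if (s % stride == 0) traj[fi++] = x;
  }
  return List::create(_["trajectory"] = traj,
                      _["hill_time"] = hill_time[Range(0, std::max(nh - 1, 0))],
                      _["hill_center"] = hill_center[Range(0, std::max(nh - 1, 0))],
                      _["hill_height"] = hill_height[Range(0, std::max(nh - 1, 0))],
                      _["n_hills"] = nh,
                      _["bias_grid"] = vgrid);
}

// Sample a discrete Markov chain from a row-stochastic matrix.
// [[Rcpp::export]]
IntegerVector markov_chain_cpp(NumericMatrix trans, int n_frames, int start) {
  const int n = trans.nrow();
  // cumulative rows
  std::vector<double> cum(n * n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      acc += trans(i, j);
      cum[i * n + j] = acc;
    }
  }
  IntegerVector out(n_frames);
  RNGScope scope;
  int state = start;
  out[0] = state;
  for (int t = 1; t < n_frames; ++t) {
    double u = unif_rand();
    const double *row = &cum[state * n];
    int j = 0;
    while (j < n - 1 && u > row[j]) ++j;
    state = j;
    out[t] = state;
  }
  return out;
}

// Energy of the built-in potentials on a vector (used for exact bias checks).
// [[Rcpp::export]]
NumericVector pot_energy_cpp(int pot_code, NumericVector pot_par,
                             NumericVector x) {
  NumericVector out(x.size());
  const double *pp = REAL(pot_par);
  for (int i = 0; i < x.size(); ++i) out[i] = pot_energy(pot_code, pp, x[i]);
  return out;
}
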