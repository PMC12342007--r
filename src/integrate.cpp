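#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Numerically stable softplus and mish.
static inline double softplus_c(double r) {
  return (r > 0.0) ? r + std::log1p(std::exp(-r)) : std::log1p(std::exp(r));
}
static inline double mish_c(double r) {
  return r * std::tanh(softplus_c(r));
}
static inline double sigmoid_c(double r) {
  return 1.0 / (1.0 + std::exp(-r));
}
// Chemical-Langevin noise scale: sqrt(z) above the threshold, z/4 below
// (continuous at the default threshold 16 since sqrt(16) = 16/4).
static inline double gnoise(double z, double thr) {
  return (z > thr) ? std::sqrt(z) : z / 4.0;
}

// Euler-Maruyama integration of the regulatory-network SDE.
//
// States are [x_1..x_n, y_1..y_n]; per step each of the 2n variables gets
// an independent Wiener increment sqrt(dt) * xi, scaled by the noise
// amplitude of its own abundance. u[t] is the light forcing evaluated at the
// step's left endpoint and enters dy of `light_gene` (1-based). Post-step
// values are clamped at `floor_`.
//
// W1: (n*h) x n stacked hidden-layer weights (gene blocks), b1: n*h biases,
// W2: h x n head weights (column per gene), b2: n head biases.
// xi: 2n x nsteps standard normals (ignored when noise_on is false).
//
// Returns a (nsteps + 1) x 2n matrix of states including the initial state.
// [[Rcpp::export(name = ".sim_core_cpp")]]
NumericMatrix sim_core_cpp(NumericVector x0, NumericVector y0,
                           NumericVector m, NumericVector delta,
                           NumericVector s, NumericVector gamma,
                           NumericMatrix W1, NumericVector b1,
                           NumericMatrix W2, NumericVector b2,
                           bool log_input,
                           double dt, int nsteps,
                           NumericMatrix xi, NumericVector u,
                           int light_gene, double noise_threshold,
                           double floor_, bool noise_on) {
  const int n = x0.size();
  const int h = W2.nrow();
  if (W1.nrow() != n * h || W1.ncol() != n || b1.size() != n * h ||
      W2.ncol() != n || b2.size() != n) {
    stop("sim_core: network parameter shapes inconsistent with n");
  }
  if (noise_on && (xi.nrow() != 2 * n || xi.ncol() < nsteps)) {
    stop("sim_core: xi must be (2n) x nsteps");
  }
  if (u.size() < nsteps) stop("sim_core: light forcing shorter than nsteps");

  NumericMatrix out(nsteps + 1, 2 * n);
  std::vector<double> x(n), y(n), r(n), hvec(n * h), f(n);
  for (int i = 0; i < n; ++i) { x[i] = x0[i]; y[i] = y0[i]; }
  for (int i = 0; i < n; ++i) { out(0, i) = x[i]; out(0, n + i) = y[i]; }
  const double sqdt = std::sqrt(dt);
  const int lg = light_gene - 1;

  for (int t = 0; t < nsteps; ++t) {
    for (int k = 0; k < n; ++k) {
      r[k] = log_input ? std::log(y[k]) : std::log1p(y[k]);
    }
    for (int j = 0; j < n * h; ++j) {
      double a = b1[j];
      for (int k = 0; k < n; ++k) a += W1(j, k) * r[k];
      hvec[j] = mish_c(a);
    }
    for (int i = 0; i < n; ++i) {
      double z = b2[i];
      for (int j = 0; j < h; ++j) z += W2(j, i) * hvec[i * h + j];
      f[i] = sigmoid_c(z);
    }
    for (int i = 0; i < n; ++i) {
      double dx = dt * (m[i] * f[i] - delta[i] * x[i]);
      double dy = dt * (s[i] * x[i] - gamma[i] * y[i]);
      if (i == lg) dy += dt * u[t];
      if (noise_on) {
        dx += gnoise(x[i], noise_threshold) * sqdt * xi(i, t);
        dy += gnoise(y[i], noise_threshold) * sqdt * xi(n + i, t);
      }
      x[i] += dx;
      y[i] += dy;
      if (x[i] < floor_) x[i] = floor_;
      if (y[i] < floor_) y[i] = floor_;
      if (!std::isfinite(x[i]) || !std::isfinite(y[i])) {
        stop("sim_core: non-finite state at t = %f (step %d)",
             (t + 1) * dt, t + 1);
      }
      out(t + 1, i) = x[i];
      out(t + 1, n + i) = y[i];
    }
  }
  return out;
}
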