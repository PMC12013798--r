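#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the coupled neural-mass network.
//
// State x = [v (m); i (m)] for m = 4 * n_sources populations. Dynamics per
// population k:
//   v_k' = i_k
//   i_k' = (H_k / tau_k) * (sum_l D[k, l] * sigma(v_l) + drive_k(t))
//          - 2 i_k / tau_k - v_k / tau_k^2
// with the zero-centred logistic sigma(v) = 1 / (1 + exp(-r v)) - 1/2, and
// drive_k(t) = sum_j C[k, j] * g_j * exp(-(t - onset_j)^2 / (2 width_j^2)).
//
// Time is in milliseconds. Returns the voltage trajectory sampled every
// `out_every` steps (m x n_out), plus a divergence flag.

static inline double sigm(double v, double r) {
  return 1.0 / (1.0 + std::exp(-r * v)) - 0.5;
}

// [[Rcpp::export(name = ".cmc_rk4")]]
List cmc_rk4(NumericMatrix D, NumericVector H, NumericVector tau,
             double r, NumericMatrix C, NumericVector onset,
             NumericVector width, NumericVector gain,
             double t0, double dt, int n_steps, int out_every,
             NumericVector x0) {
  const int m = D.nrow();
  const int nin = C.ncol();
  std::vector<double> v(m), cur(m), Ht(m), i2t(m), it2(m);
  for (int k = 0; k < m; ++k) {
    v[k] = x0[k];
    cur[k] = x0[m + k];
    Ht[k] = H[k] / tau[k];
    i2t[k] = 2.0 / tau[k];
    it2[k] = 1.0 / (tau[k] * tau[k]);
  }
  const int n_out = n_steps / out_every + 1;
  NumericMatrix out(m, n_out);
  for (int k = 0; k < m; ++k) out(k, 0) = v[k];

  std::vector<double> kv1(m), ki1(m), kv2(m), ki2(m), kv3(m), ki3(m),
      kv4(m), ki4(m), tv(m), ti(m), sig(m);
  bool diverged = false;
  double t_div = NA_REAL;
  int col = 1;

  auto deriv = [&](const std::vector<double>& vv,
                   const std::vector<double>& ii, double t,
                   std::vector<double>& dv, std::vector<double>& di) {
    for (int k = 0; k < m; ++k) sig[k] = sigm(vv[k], r);
    for (int k = 0; k < m; ++k) {
      double s = 0.0;
      for (int l = 0; l < m; ++l) s += D(k, l) * sig[l];
      for (int j = 0; j < nin; ++j) {
        double z = (t - onset[j]) / width[j];
        s += C(k, j) * gain[j] * std::exp(-0.5 * z * z);
      }
      dv[k] = ii[k];
      di[k] = Ht[k] * s - i2t[k] * ii[k] - it2[k] * vv[k];
    }
  };

  double t = t0;
  for (int step = 1; step <= n_steps; ++step) {
    deriv(v, cur, t, kv1, ki1);
    for (int k = 0; k < m; ++k) { tv[k] = v[k] + 0.5 * dt * kv1[k];
                                  ti[k] = cur[k] + 0.5 * dt * ki1[k]; }
    deriv(tv, ti, t + 0.5 * dt, kv2, ki2);
    for (int k = 0; k < m; ++k) { tv[k] = v[k] + 0.5 * dt * kv2[k];
                                  ti[k] = cur[k] + 0.5 * dt * ki2[k]; }
    deriv(tv, ti, t + 0.5 * dt, kv3, ki3);
    for (int k = 0; k < m; ++k) { tv[k] = v[k] + dt * kv3[k];
                                  ti[k] = cur[k] + dt * ki3[k]; }
    deriv(tv, ti, t + dt, kv4, ki4);
    for (int k = 0; k < m; ++k) {
      v[k] += dt / 6.0 * (kv1[k] + 2 * kv2[k] + 2 * kv3[k] + kv4[k]);
      cur[k] += dt / 6.0 * (ki1[k] + 2 * ki2[k] + 2 * ki3[k] + ki4[k]);
      if (!std::isfinite(v[k]) || std::fabs(v[k]) > 1e9) diverged = true;
    }
    t = t0 + step * dt;
    if (diverged) { t_div = t; break; }
    if (step % out_every == 0 && col < n_out) {
      for (int k = 0; k < m; ++k) out(k, col) = v[k];
      ++col;
    }
  }
  return List::create(_["v"] = out, _["diverged"] = diverged,
                      _["t_diverged"] = t_div);
}
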