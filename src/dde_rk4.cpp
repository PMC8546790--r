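#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Method-of-steps RK4 integrator for the constant-lag tumor-immune system
//   x' = -x + y_d z_d / (1 + z_d)
//   y' = a1 x - a2 y + a3
//   z' = a4 z - y_d z_d
// with (y_d, z_d) the state one delay in the past.
//
// The step h divides the delay exactly (delta = n_lag * h), so breakpoints
// at integer multiples of the delay are mesh points and the delayed-stage
// lookups are either stored nodes (k1, k4) or interval midpoints (k2, k3),
// where a cubic Hermite interpolant built from stored values and slopes is
// locally O(h^4). History nodes keep their own slope array so that the
// derivative jump at t = 0 never contaminates the interpolant.

static inline void ti_rhs(const double* u, double yd, double zd,
                          const double* a, double* out) {
  out[0] = -u[0] + yd * zd / (1.0 + zd);
  out[1] = a[0] * u[0] - a[1] * u[1] + a[2];
  out[2] = a[3] * u[2] - yd * zd;
}

static inline double hermite_mid(double y0, double y1, double f0, double f1,
                                 double h) {
  return 0.5 * (y0 + y1) + 0.125 * h * (f0 - f1);
}

// [[Rcpp::export(name = ".dde_rk4_cpp")]]
List dde_rk4_cpp(NumericVector a, double h, int n_lag, double n_steps_d,
                 NumericMatrix hist_vals, NumericMatrix hist_slopes,
                 int out_every, double overflow) {
  const long long n_steps = (long long)n_steps_d;
  const int nbuf = n_lag + 2;            // ring buffer for solution nodes
  std::vector<double> sv((size_t)nbuf * 3), sd((size_t)nbuf * 3);
  const double* ap = REAL(a);

  // history arrays: node j = -n_lag..0 stored at column j + n_lag
  // (values and exact/supplied slopes of the history function)
  if (hist_vals.nrow() != n_lag + 1 || hist_vals.ncol() != 3)
    stop("hist_vals must be (n_lag + 1) x 3");

  // solution node 0 = history at theta = 0, slope = rhs(0+)
  double u0[3] = { hist_vals(n_lag, 0), hist_vals(n_lag, 1), hist_vals(n_lag, 2) };
  double f0[3];
  ti_rhs(u0, hist_vals(0, 1), hist_vals(0, 2), ap, f0);
  for (int c = 0; c < 3; ++c) { sv[c] = u0[c]; sd[c] = f0[c]; }

  long long n_out_max = n_steps / out_every + 2;
  NumericVector out_t(n_out_max);
  NumericMatrix out_y(n_out_max, 3);
  long long n_out = 0;
  out_t[0] = 0.0;
  for (int c = 0; c < 3; ++c) out_y(0, c) = u0[c];
  n_out = 1;

  double min_y = u0[1], min_z = u0[2];
  for (int j = 0; j <= n_lag; ++j) {
    if (hist_vals(j, 1) < min_y) min_y = hist_vals(j, 1);
    if (hist_vals(j, 2) < min_z) min_z = hist_vals(j, 2);
  }

  bool diverged = false;
  long long s_final = 0;

  // delayed value (y, z) at node q (q may index into the history)
  auto node_yz = [&](long long q, double* yz) {
    if (q <= 0) {
      int jc = (int)(q + n_lag);
      yz[0] = hist_vals(jc, 1); yz[1] = hist_vals(jc, 2);
    } else {
      size_t slot = (size_t)(q % nbuf) * 3;
      yz[0] = sv[slot + 1]; yz[1] = sv[slot + 2];
    }
  };
  // delayed value at the midpoint of [q, q+1]
  auto mid_yz = [&](long long q, double* yz) {
    if (q + 1 <= 0) {
      int jc = (int)(q + n_lag);
      for (int c = 1; c < 3; ++c)
        yz[c - 1] = hermite_mid(hist_vals(jc, c), hist_vals(jc + 1, c),
                                hist_slopes(jc, c), hist_slopes(jc + 1, c), h);
    } else {
      size_t s0 = (size_t)(q % nbuf) * 3, s1 = (size_t)((q + 1) % nbuf) * 3;
      for (int c = 1; c < 3; ++c)
        yz[c - 1] = hermite_mid(sv[s0 + c], sv[s1 + c],
                                sd[s0 + c], sd[s1 + c], h);
    }
  };

  double u[3], k1[3], k2[3], k3[3], k4[3], ut[3], dl[2];
  for (long long s = 0; s < n_steps; ++s) {
    size_t cs = (size_t)(s % nbuf) * 3;
    for (int c = 0; c < 3; ++c) { u[c] = sv[cs + c]; k1[c] = sd[cs + c]; }

    mid_yz(s - n_lag, dl);
    if (dl[1] <= -1.0 + 1e-12) { diverged = true; s_final = s; break; }
    for (int c = 0; c < 3; ++c) ut[c] = u[c] + 0.5 * h * k1[c];
    ti_rhs(ut, dl[0], dl[1], ap, k2);
    for (int c = 0; c < 3; ++c) ut[c] = u[c] + 0.5 * h * k2[c];
    ti_rhs(ut, dl[0], dl[1], ap, k3);

    node_yz(s - n_lag + 1, dl);
    if (dl[1] <= -1.0 + 1e-12) { diverged = true; s_final = s; break; }
    for (int c = 0; c < 3; ++c) ut[c] = u[c] + h * k3[c];
    ti_rhs(ut, dl[0], dl[1], ap, k4);

    size_t ns = (size_t)((s + 1) % nbuf) * 3;
    bool bad = false;
    for (int c = 0; c < 3; ++c) {
      double v = u[c] + h / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
      if (!std::isfinite(v) || std::fabs(v) > overflow) bad = true;
      sv[ns + c] = v;
    }
    s_final = s + 1;
    if (bad) { diverged = true; break; }
    if (sv[ns + 1] < min_y) min_y = sv[ns + 1];
    if (sv[ns + 2] < min_z) min_z = sv[ns + 2];

    node_yz(s + 1 - n_lag, dl);
    if (dl[1] <= -1.0 + 1e-12) { diverged = true; break; }
    ti_rhs(&sv[ns], dl[0], dl[1], ap, &sd[ns]);

    if ((s + 1) % out_every == 0 || s + 1 == n_steps) {
      out_t[n_out] = (double)(s + 1) * h;
      for (int c = 0; c < 3; ++c) out_y(n_out, c) = sv[ns + c];
      ++n_out;
    }
    if (s % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  // truncate the output containers to what was actually produced
  NumericVector tt(n_out);
  NumericMatrix yy(n_out, 3);
  for (long long i = 0; i < n_out; ++i) {
    tt[i] = out_t[i];
    for (int c = 0; c < 3; ++c) yy(i, c) = out_y(i, c);
  }
  return List::create(_["times"] = tt, _["states"] = yy,
                      _["diverged"] = diverged,
                      _["min_y"] = min_y, _["min_z"] = min_z,
                      _["steps"] = (double)s_final);
}
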