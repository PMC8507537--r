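#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete causal convolution of exp(-t/tau) with u, scaled by dt:
//   y[k] = dt * sum_{j<=k} u[j] exp(-(k-j) dt / tau)
// via the exact O(n) recursion y[k] = e^{-dt/tau} y[k-1] + dt u[k].
static void conv_exp_core(const double* u, int nu, double dt, double tau,
                          int n, double* out) {
  double a = std::exp(-dt / tau);
  double prev = 0.0;
  for (int k = 0; k < n; ++k) {
    double uk = (k < nu) ? u[k] : 0.0;
    prev = a * prev + dt * uk;
    out[k] = prev;
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_exp(NumericVector u, double dt, double tau, int n) {
  NumericVector out(n);
  conv_exp_core(u.begin(), u.size(), dt, tau, n, out.begin());
  return out;
}

// Solve the k x k SPD system G a = c by Gaussian elimination (k <= 3).
static bool solve_small(double G[3][3], double c[3], int k, double a[3]) {
  double M[3][4];
  for (int i = 0; i < k; ++i) {
    for (int j = 0; j < k; ++j) M[i][j] = G[i][j];
    M[i][k] = c[i];
  }
  for (int col = 0; col < k; ++col) {
    int piv = col;
    for (int r = col + 1; r < k; ++r)
      if (std::fabs(M[r][col]) > std::fabs(M[piv][col])) piv = r;
    if (std::fabs(M[piv][col]) < 1e-300) return false;
    if (piv != col)
      for (int j = 0; j <= k; ++j) std::swap(M[piv][j], M[col][j]);
    for (int r = 0; r < k; ++r) {
      if (r == col) continue;
      double f = M[r][col] / M[col][col];
      for (int j = col; j <= k; ++j) M[r][j] -= f * M[col][j];
    }
  }
  for (int i = 0; i < k; ++i) a[i] = M[i][k] / M[i][i];
  return true;
}

// Variable-projection inner solve: given component lifetimes, build the
// reconvolved exponential basis and find the nonnegative least-squares
// amplitudes exactly by enumerating active sets (k <= 3). Returns the SSE
// and fills a_out (length k).
static double vp_core(const double* taus, int k, const double* u, int nu,
                      double dt, const double* y, int n, double* a_out,
                      double* work /* k*n scratch */) {
  for (int j = 0; j < k; ++j)
    conv_exp_core(u, nu, dt, taus[j], n, work + (size_t)j * n);
  double G[3][3], c[3], yty = 0.0;
  for (int i = 0; i < n; ++i) yty += y[i] * y[i];
  for (int i = 0; i < k; ++i) {
    const double* Bi = work + (size_t)i * n;
    for (int j = i; j < k; ++j) {
      const double* Bj = work + (size_t)j * n;
      double s = 0.0;
      for (int t = 0; t < n; ++t) s += Bi[t] * Bj[t];
      G[i][j] = G[j][i] = s;
    }
    double s = 0.0;
    for (int t = 0; t < n; ++t) s += Bi[t] * y[t];
    c[i] = s;
  }
  double best_sse = yty;                 // empty active set: a = 0
  double best_a[3] = {0.0, 0.0, 0.0};
  for (int bits = 1; bits < (1 << k); ++bits) {
    int idx[3], m = 0;
    for (int j = 0; j < k; ++j) if (bits & (1 << j)) idx[m++] = j;
    double Gs[3][3], cs[3], as[3];
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < m; ++j) Gs[i][j] = G[idx[i]][idx[j]];
      cs[i] = c[idx[i]];
    }
    if (!solve_small(Gs, cs, m, as)) continue;
    bool ok = true;
    for (int i = 0; i < m; ++i) if (as[i] < 0 || !R_finite(as[i])) ok = false;
    if (!ok) continue;
    double sse = yty;                    // at the LS optimum: y'y - a'c
    for (int i = 0; i < m; ++i) sse -= as[i] * cs[i];
    if (sse < best_sse) {
      best_sse = sse;
      for (int j = 0; j < 3; ++j) best_a[j] = 0.0;
      for (int i = 0; i < m; ++i) best_a[idx[i]] = as[i];
    }
  }
  if (best_sse < 0) best_sse = 0;        // numerical guard
  for (int j = 0; j < k; ++j) a_out[j] = best_a[j];
  return best_sse;
}

// [[Rcpp::export]]
List cpp_vp_fit(NumericVector taus, NumericVector u, double dt,
                NumericVector y) {
  int k = taus.size();
  if (k < 1 || k > 3) stop("1 to 3 components supported");
  int n = y.size();
  std::vector<double> work((size_t)k * n);
  double a[3];
  double sse = vp_core(taus.begin(), k, u.begin(), u.size(), dt,
                       y.begin(), n, a, work.data());
  NumericVector av(k);
  for (int j = 0; j < k; ++j) av[j] = a[j];
  return List::create(_["a"] = av, _["sse"] = sse);
}

// Objective for the 2-component fit: SSE at clamped log-lifetimes with a
// quadratic out-of-bounds penalty factor (mirrors the R-side objective).
static double biexp_obj(double lt1, double lt2, const double* u, int nu,
                        double dt, const double* y, int n, double lo,
                        double hi, double* work) {
  double pen = 0.0;
  double l1 = lt1, l2 = lt2;
  if (l1 > hi) { pen += (l1 - hi) * (l1 - hi); l1 = hi; }
  if (l1 < lo) { pen += (lo - l1) * (lo - l1); l1 = lo; }
  if (l2 > hi) { pen += (l2 - hi) * (l2 - hi); l2 = hi; }
  if (l2 < lo) { pen += (lo - l2) * (lo - l2); l2 = lo; }
  double taus[2] = {std::exp(l1), std::exp(l2)};
  double a[3];
  double sse = vp_core(taus, 2, u, nu, dt, y, n, a, work);
  return sse * (1.0 + pen);
}

// Nelder-Mead over (log tau_fast, log tau_slow) with multi-start and
// variable-projection amplitudes; returns the best solution across starts.
// [[Rcpp::export]]
List cpp_biexp_fit(NumericVector y, NumericVector u, double dt,
                   NumericMatrix starts, double tau_min, double tau_max,
                   int maxit, double reltol) {
  double lo = std::log(tau_min), hi = std::log(tau_max);
  int n = y.size(), nu = u.size();
  const double* yp = y.begin();
  const double* up = u.begin();
  std::vector<double> work((size_t)2 * n);
  double* w = work.data();
  double best_f = R_PosInf;
  double best_x[2] = {0, 0};
  int best_it = 0;
  bool best_conv = false;

  for (int s = 0; s < starts.nrow(); ++s) {
    double p[3][2], f[3];
    p[0][0] = std::log(starts(s, 0)); p[0][1] = std::log(starts(s, 1));
    for (int v = 1; v < 3; ++v) {       // optim-style 10% initial steps
      p[v][0] = p[0][0]; p[v][1] = p[0][1];
      double step = 0.1 * std::fabs(p[0][v - 1]);
      if (step < 0.1) step = 0.1;
      p[v][v - 1] += step;
    }
    for (int v = 0; v < 3; ++v)
      f[v] = biexp_obj(p[v][0], p[v][1], up, nu, dt, yp, n, lo, hi, w);
    int it = 0;
    bool conv = false;
    while (it < maxit) {
      int l = 0, h = 0;
      for (int v = 1; v < 3; ++v) {
        if (f[v] < f[l]) l = v;
        if (f[v] > f[h]) h = v;
      }
      if (std::fabs(f[h] - f[l]) <=
          reltol * (std::fabs(f[l]) + reltol)) { conv = true; break; }
      double cx = 0, cy = 0;            // centroid excluding worst
      for (int v = 0; v < 3; ++v) if (v != h) { cx += p[v][0]; cy += p[v][1]; }
      cx /= 2; cy /= 2;
      double rx = cx + (cx - p[h][0]), ry = cy + (cy - p[h][1]);
      double fr = biexp_obj(rx, ry, up, nu, dt, yp, n, lo, hi, w); ++it;
      if (fr < f[l]) {
        double ex = cx + 2 * (cx - p[h][0]), ey = cy + 2 * (cy - p[h][1]);
        double fe = biexp_obj(ex, ey, up, nu, dt, yp, n, lo, hi, w); ++it;
        if (fe < fr) { p[h][0] = ex; p[h][1] = ey; f[h] = fe; }
        else { p[h][0] = rx; p[h][1] = ry; f[h] = fr; }
      } else {
        int worse = 0;
        for (int v = 0; v < 3; ++v) if (fr >= f[v]) ++worse;
        if (worse >= 2) {               // no better than second worst
          if (fr < f[h]) { p[h][0] = rx; p[h][1] = ry; f[h] = fr; }
          double kx = cx + 0.5 * (p[h][0] - cx), ky = cy + 0.5 * (p[h][1] - cy);
          double fk = biexp_obj(kx, ky, up, nu, dt, yp, n, lo, hi, w); ++it;
          if (fk < f[h]) { p[h][0] = kx; p[h][1] = ky; f[h] = fk; }
          else {                        // shrink toward best
            for (int v = 0; v < 3; ++v) {
              if (v == l) continue;
              p[v][0] = p[l][0] + 0.5 * (p[v][0] - p[l][0]);
              p[v][1] = p[l][1] + 0.5 * (p[v][1] - p[l][1]);
              f[v] = biexp_obj(p[v][0], p[v][1], up, nu, dt, yp, n, lo, hi, w);
              ++it;
            }
          }
        } else { p[h][0] = rx; p[h][1] = ry; f[h] = fr; }
      }
    }
    int l = 0;
    for (int v = 1; v < 3; ++v) if (f[v] < f[l]) l = v;
    if (f[l] < best_f) {
      best_f = f[l]; best_x[0] = p[l][0]; best_x[1] = p[l][1];
      best_it = it; best_conv = conv;
    }
  }
  return List::create(_["par"] = NumericVector::create(best_x[0], best_x[1]),
                      _["value"] = best_f,
                      _["iterations"] = best_it,
                      _["converged"] = best_conv);
}
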