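// Low-level preprocessing kernels for Raman spectra.
// All routines operate on a single intensity vector; *_mat variants loop
// over the rows of a spectra matrix so the R-level pipeline stays fast.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static double median_of(std::vector<double> v) {
  const size_t n = v.size();
  if (n == 0) return NA_REAL;
  std::nth_element(v.begin(), v.begin() + n / 2, v.end());
  double hi = v[n / 2];
  if (n % 2 == 1) return hi;
  std::nth_element(v.begin(), v.begin() + n / 2 - 1, v.end());
  return 0.5 * (hi + v[n / 2 - 1]);
}

// Second difference of y at interior channels; d[i] refers to channel i,
// i in [1, p-2]. Channels 0 and p-1 have no curvature estimate and are
// never flagged.
static void second_diff(const std::vector<double>& y, std::vector<double>& d) {
  const int p = (int)y.size();
  d.assign(p, 0.0);
  for (int i = 1; i < p - 1; ++i) d[i] = y[i + 1] - 2.0 * y[i] + y[i - 1];
}

// Modified z-score of d[i]: centred on the rolling median of a window of
// the second-difference series (window clamped at the edges), scaled by
// the larger of the rolling MAD and the spectrum-wide MAD. The global term
// stabilizes the scale against the heavy tails of small-window MAD
// estimates in noisy flat regions; the local term keeps sharp genuine
// bands (locally high curvature) from being flagged in noise-free
// spectra. A tiny floor exposes isolated spikes in perfectly flat
// neighbourhoods.
static double mod_z(const std::vector<double>& d, int i, int half, int p,
                    double global_mad, double mad_floor) {
  int lo = std::max(1, i - half), hi = std::min(p - 2, i + half);
  std::vector<double> win(d.begin() + lo, d.begin() + hi + 1);
  double m = median_of(win);
  for (double& w : win) w = std::fabs(w - m);
  double mad = std::max(median_of(win), global_mad);
  if (mad < mad_floor) mad = mad_floor;
  return 0.6745 * (d[i] - m) / mad;
}

// MAD of the interior second differences (about their median)
static double global_mad_of(const std::vector<double>& d, int p) {
  if (p < 4) return 0.0;
  std::vector<double> v(d.begin() + 1, d.begin() + (p - 1));
  double m = median_of(v);
  for (double& w : v) w = std::fabs(w - m);
  return median_of(v);
}

// Linear interpolation across a set of flagged channels using the nearest
// unflagged neighbours; at the edges the nearest clean value is extended.
static void interp_flagged(std::vector<double>& y,
                           const std::vector<char>& flagged) {
  const int p = (int)y.size();
  for (int i = 0; i < p; ++i) {
    if (!flagged[i]) continue;
    int l = i - 1, r = i + 1;
    while (l >= 0 && flagged[l]) --l;
    while (r < p && flagged[r]) ++r;
    if (l >= 0 && r < p) {
      double t = double(i - l) / double(r - l);
      y[i] = y[l] + t * (y[r] - y[l]);
    } else if (l >= 0) {
      y[i] = y[l];
    } else if (r < p) {
      y[i] = y[r];
    } else {
      stop("despike: every channel flagged (degenerate spectrum)");
    }
  }
}

// Iterative despiker: repeatedly flag the single worst channel by modified
// z-score of the second difference, replace it by linear interpolation of
// the nearest clean neighbours, and re-examine the (locally updated)
// curvature. One-at-a-time removal keeps precision high: the shoulders of a
// spike regain normal curvature as soon as the spike channel itself is
// repaired, so they are not flagged.
// [[Rcpp::export]]
List despike_cpp(NumericVector yr, int window, double z_threshold) {
  const int p = yr.size();
  if (p < 3) return List::create(_["intensity"] = clone(yr),
                                 _["flagged"] = IntegerVector(0));
  if (window < 3 || window % 2 == 0)
    stop("despike window must be odd and >= 3");
  const int half = window / 2;

  std::vector<double> y(yr.begin(), yr.end());
  double ymax = 0.0;
  for (double v : y) ymax = std::max(ymax, std::fabs(v));
  const double mad_floor = std::max(1e-12, 1e-9 * ymax);

  std::vector<char> flagged(p, 0);
  std::vector<double> d;
  std::vector<int> flags;
  const int max_iter = p;

  for (int iter = 0; iter < max_iter; ++iter) {
    second_diff(y, d);
    const double gmad = global_mad_of(d, p);
    double worst = 0.0;
    int worst_i = -1;
    for (int i = 1; i < p - 1; ++i) {
      if (flagged[i]) continue;
      double z = std::fabs(mod_z(d, i, half, p, gmad, mad_floor));
      if (z > worst) { worst = z; worst_i = i; }
    }
    if (worst_i < 0 || worst <= z_threshold) break;
    flagged[worst_i] = 1;
    flags.push_back(worst_i);
    int n_flagged = 0;
    for (char f : flagged) n_flagged += f;
    if (n_flagged >= p - 2)
      stop("despike: every channel flagged (degenerate spectrum)");
    interp_flagged(y, flagged);
  }

  std::sort(flags.begin(), flags.end());
  IntegerVector fl(flags.size());
  for (size_t i = 0; i < flags.size(); ++i) fl[i] = flags[i] + 1; // 1-based
  return List::create(_["intensity"] = NumericVector(y.begin(), y.end()),
                      _["flagged"] = fl);
}

// [[Rcpp::export]]
List despike_mat_cpp(NumericMatrix X, int window, double z_threshold) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  List flags(n);
  NumericVector row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    List r = despike_cpp(row, window, z_threshold);
    NumericVector cl = r["intensity"];
    for (int j = 0; j < p; ++j) out(i, j) = cl[j];
    flags[i] = r["flagged"];
  }
  return List::create(_["intensity"] = out, _["flagged"] = flags);
}

// Asymmetric least squares baseline (Eilers & Boelens style):
// minimize sum_i w_i (y_i - z_i)^2 + lambda * sum (Delta^2 z)^2 with
// asymmetric weights w_i = p for y_i > z_i, 1 - p otherwise.
// The normal equations (W + lambda D'D) z = W y form a pentadiagonal SPD
// system solved by banded Cholesky (LDL'), O(p) per iteration.
// [[Rcpp::export]]
NumericVector als_baseline_cpp(NumericVector yr, double lambda, double p_asym,
                               int iters) {
  const int p = yr.size();
  if (p < 4) stop("spectrum too short for baseline estimation");
  for (int i = 0; i < p; ++i)
    if (!std::isfinite(yr[i])) stop("non-finite intensity in baseline fit");

  // constant bands of lambda * D'D (D = second-difference operator)
  std::vector<double> d0(p), d1(p - 1), d2(p - 2, lambda);
  for (int j = 0; j < p; ++j) {
    double v;
    if (j == 0 || j == p - 1) v = 1.0;
    else if (j == 1 || j == p - 2) v = 5.0;
    else v = 6.0;
    d0[j] = lambda * v;
  }
  for (int j = 0; j < p - 1; ++j) {
    double v = (j == 0 || j == p - 2) ? -2.0 : -4.0;
    d1[j] = lambda * v;
  }

  std::vector<double> w(p, 1.0), z(p, 0.0);
  std::vector<double> a0(p), a1(p - 1), a2(p - 2);
  std::vector<double> l1(p - 1), l2(p - 2), diag(p), rhs(p);

  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < p; ++j) { a0[j] = d0[j] + w[j]; rhs[j] = w[j] * yr[j]; }
    std::copy(d1.begin(), d1.end(), a1.begin());
    std::copy(d2.begin(), d2.end(), a2.begin());

    // banded LDL' factorization, bandwidth 2
    for (int j = 0; j < p; ++j) {
      double dj = a0[j];
      if (j >= 1) dj -= l1[j - 1] * l1[j - 1] * diag[j - 1];
      if (j >= 2) dj -= l2[j - 2] * l2[j - 2] * diag[j - 2];
      diag[j] = dj;
      if (j + 1 < p) {
        double v = a1[j];
        if (j >= 1) v -= l1[j - 1] * diag[j - 1] * l2[j - 1];
        l1[j] = v / dj;
      }
      if (j + 2 < p) l2[j] = a2[j] / dj;
    }
    // forward solve L u = rhs (u stored in z)
    for (int j = 0; j < p; ++j) {
      double v = rhs[j];
      if (j >= 1) v -= l1[j - 1] * z[j - 1];
      if (j >= 2) v -= l2[j - 2] * z[j - 2];
      z[j] = v;
    }
    // diagonal + backward solve L' z = u
    for (int j = 0; j < p; ++j) z[j] /= diag[j];
    for (int j = p - 1; j >= 0; --j) {
      double v = z[j];
      if (j + 1 < p) v -= l1[j] * z[j + 1];
      if (j + 2 < p) v -= l2[j] * z[j + 2];
      z[j] = v;
    }
    for (int j = 0; j < p; ++j) w[j] = (yr[j] > z[j]) ? p_asym : 1.0 - p_asym;
  }
  return NumericVector(z.begin(), z.end());
}

// [[Rcpp::export]]
NumericMatrix als_baseline_mat_cpp(NumericMatrix X, double lambda,
                                   double p_asym, int iters) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  NumericVector row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    NumericVector b = als_baseline_cpp(row, lambda, p_asym, iters);
    for (int j = 0; j < p; ++j) out(i, j) = b[j];
  }
  return out;
}

// scipy-style 'reflect' index (edge element included): -1 -> 0, p -> p-1
static inline int reflect_idx(int t, int p) {
  while (t < 0 || t >= p) {
    if (t < 0) t = -t - 1;
    if (t >= p) t = 2 * p - 1 - t;
  }
  return t;
}

// Discrete Gaussian convolution, kernel truncated at 4 sigma and
// renormalized to unit sum, reflect boundary handling.
// [[Rcpp::export]]
NumericVector gauss_smooth_cpp(NumericVector yr, double sigma) {
  const int p = yr.size();
  if (sigma <= 0) stop("smoothing sigma must be > 0");
  const int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int j = -r; j <= r; ++j) {
    k[j + r] = std::exp(-0.5 * j * j / (sigma * sigma));
    s += k[j + r];
  }
  for (double& v : k) v /= s;
  NumericVector out(p);
  for (int i = 0; i < p; ++i) {
    double acc = 0.0;
    for (int j = -r; j <= r; ++j) acc += k[j + r] * yr[reflect_idx(i + j, p)];
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix gauss_smooth_mat_cpp(NumericMatrix X, double sigma) {
  const int n = X.nrow(), p = X.ncol();
  NumericMatrix out(n, p);
  NumericVector row(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    NumericVector sm = gauss_smooth_cpp(row, sigma);
    for (int j = 0; j < p; ++j) out(i, j) = sm[j];
  }
  return out;
}
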