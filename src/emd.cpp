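// Core empirical-mode-decomposition primitives.
//
// Everything here works on 0-based sample indices as the abscissa; the R
// wrappers translate to 1-based indices for the user-facing API.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Extrema detection with plateau handling (plateau -> middle index).
// Returns strict interior local maxima and minima, alternating by nature.
static void find_extrema_core(const NumericVector& x,
                              std::vector<double>& tmax, std::vector<double>& vmax,
                              std::vector<double>& tmin, std::vector<double>& vmin) {
  const int n = x.size();
  tmax.clear(); vmax.clear(); tmin.clear(); vmin.clear();
  int i = 1;
  while (i < n - 1) {
    if (x[i] == x[i - 1]) { ++i; continue; }
    // locate the end of any plateau starting at i
    int j = i;
    while (j < n - 1 && x[j + 1] == x[i]) ++j;
    if (j >= n - 1) break;               // plateau runs into the boundary
    const double left = x[i - 1], mid = x[i], right = x[j + 1];
    const int idx = (i + j) / 2;         // plateau midpoint (single sample if i==j)
    if (mid > left && mid > right) { tmax.push_back(idx); vmax.push_back(mid); }
    else if (mid < left && mid < right) { tmin.push_back(idx); vmin.push_back(mid); }
    i = j + 1;
  }
}

// [[Rcpp::export]]
List cpp_find_extrema(NumericVector x) {
  std::vector<double> tmax, vmax, tmin, vmin;
  find_extrema_core(x, tmax, vmax, tmin, vmin);
  return List::create(_["max_idx"] = wrap(tmax), _["max_val"] = wrap(vmax),
                      _["min_idx"] = wrap(tmin), _["min_val"] = wrap(vmin));
}

// ---------------------------------------------------------------------------
// Natural cubic spline through (t, v), evaluated at 0..n-1.
// Knots must be strictly increasing and cover [0, n-1].
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& v,
                                int n, std::vector<double>& out) {
  const int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 1) { for (int q = 0; q < n; ++q) out[q] = v[0]; return; }
  if (m == 2) {
    const double slope = (v[1] - v[0]) / (t[1] - t[0]);
    for (int q = 0; q < n; ++q) out[q] = v[0] + slope * (q - t[0]);
    return;
  }
  // second derivatives M, natural boundary: M[0] = M[m-1] = 0 (Thomas algorithm)
  std::vector<double> h(m - 1), alpha(m), l(m), mu(m), z(m), M(m);
  for (int k = 0; k < m - 1; ++k) h[k] = t[k + 1] - t[k];
  for (int k = 1; k < m - 1; ++k)
    alpha[k] = 6.0 * ((v[k + 1] - v[k]) / h[k] - (v[k] - v[k - 1]) / h[k - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int k = 1; k < m - 1; ++k) {
    l[k] = 2.0 * (t[k + 1] - t[k - 1]) - h[k - 1] * mu[k - 1];
    mu[k] = h[k] / l[k];
    z[k] = (alpha[k] - h[k - 1] * z[k - 1]) / l[k];
  }
  M[m - 1] = 0.0;
  for (int k = m - 2; k >= 0; --k) M[k] = z[k] - mu[k] * M[k + 1];
  // evaluate; queries are sorted so walk the segments once
  int seg = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = (double)q;
    while (seg < m - 2 && t[seg + 1] < xq) ++seg;
    const double hk = h[seg], a = (t[seg + 1] - xq) / hk, b = (xq - t[seg]) / hk;
    out[q] = a * v[seg] + b * v[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) * (hk * hk) / 6.0;
  }
}

// Extend an extrema sequence by mirroring the two extrema nearest to each
// boundary across the signal end points (t = 0 and t = n-1).
static void mirror_extend(std::vector<double>& t, std::vector<double>& v, int n) {
  const int m = (int)t.size();
  if (m == 0) return;
  std::vector<double> t2, v2;
  const int nl = std::min(2, m);
  for (int k = nl - 1; k >= 0; --k) { t2.push_back(-t[k]); v2.push_back(v[k]); }
  for (int k = 0; k < m; ++k) { t2.push_back(t[k]); v2.push_back(v[k]); }
  for (int k = m - 1; k >= std::max(0, m - 2); --k) {
    t2.push_back(2.0 * (n - 1) - t[k]); v2.push_back(v[k]);
  }
  t.swap(t2); v.swap(v2);
}

// boundary: 0 = mirror, 1 = clamp (signal end points join both envelopes)
static bool local_mean_core(const NumericVector& x, int boundary,
                            std::vector<double>& mean_env) {
  const int n = x.size();
  std::vector<double> tmax, vmax, tmin, vmin;
  find_extrema_core(x, tmax, vmax, tmin, vmin);
  if (tmax.empty() || tmin.empty()) return false;
  if (boundary == 1) {
    tmax.insert(tmax.begin(), 0.0); vmax.insert(vmax.begin(), x[0]);
    tmax.push_back(n - 1.0);        vmax.push_back(x[n - 1]);
    tmin.insert(tmin.begin(), 0.0); vmin.insert(vmin.begin(), x[0]);
    tmin.push_back(n - 1.0);        vmin.push_back(x[n - 1]);
  } else {
    mirror_extend(tmax, vmax, n);
    mirror_extend(tmin, vmin, n);
  }
  std::vector<double> upper, lower;
  natural_spline_eval(tmax, vmax, n, upper);
  natural_spline_eval(tmin, vmin, n, lower);
  mean_env.resize(n);
  for (int q = 0; q < n; ++q) mean_env[q] = 0.5 * (upper[q] + lower[q]);
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_local_mean(NumericVector x, int boundary) {
  std::vector<double> m;
  if (!local_mean_core(x, boundary, m)) return NumericVector(0);
  return wrap(m);
}

static int zero_crossings_core(const std::vector<double>& x) {
  int count = 0, prev = 0;
  for (size_t q = 0; q < x.size(); ++q) {
    const int s = (x[q] > 0.0) - (x[q] < 0.0);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++count;
    prev = s;
  }
  return count;
}

// ---------------------------------------------------------------------------
// One sifting loop: subtract the local mean until the stopping criterion is
// met.  criterion 0: Cauchy SD, sum((h_prev-h)^2)/sum(h_prev^2) < threshold.
// criterion 1: S-number, extrema and zero-crossing counts differ by at most
// one and stay unchanged for s_number consecutive passes (the setting that
// gives white noise its dyadic filter-bank splitting).
static bool sift_core(const NumericVector& x, int criterion,
                      double stop_threshold, int s_number,
                      int max_siftings, int boundary,
                      std::vector<double>& imf, int& nsift) {
  const int n = x.size();
  imf.assign(x.begin(), x.end());
  nsift = 0;
  std::vector<double> m;
  int stable = 0, prev_ne = -1, prev_zc = -1;
  for (int s = 0; s < max_siftings; ++s) {
    NumericVector h(imf.begin(), imf.end());
    if (!local_mean_core(h, boundary, m)) return nsift > 0;
    double num = 0.0, den = 0.0;
    for (int q = 0; q < n; ++q) {
      num += m[q] * m[q];
      den += imf[q] * imf[q];
      imf[q] -= m[q];
    }
    ++nsift;
    if (criterion == 0) {
      if (den <= 0.0) return false;
      if (num / den < stop_threshold) return true;
    } else {
      std::vector<double> tmax, vmax, tmin, vmin;
      NumericVector hv(imf.begin(), imf.end());
      find_extrema_core(hv, tmax, vmax, tmin, vmin);
      const int ne = (int)(tmax.size() + tmin.size());
      const int zc = zero_crossings_core(imf);
      if (std::abs(ne - zc) <= 1 && ne == prev_ne && zc == prev_zc) ++stable;
      else stable = 0;
      prev_ne = ne; prev_zc = zc;
      if (stable >= s_number) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_sift(NumericVector x, int criterion, double stop_threshold,
              int s_number, int max_siftings, int boundary) {
  std::vector<double> imf; int nsift;
  const bool conv = sift_core(x, criterion, stop_threshold, s_number,
                              max_siftings, boundary, imf, nsift);
  return List::create(_["imf"] = wrap(imf), _["converged"] = conv,
                      _["n_siftings"] = nsift);
}

// [[Rcpp::export]]
int cpp_n_interior_extrema(NumericVector x) {
  std::vector<double> tmax, vmax, tmin, vmin;
  find_extrema_core(x, tmax, vmax, tmin, vmin);
  return (int)(tmax.size() + tmin.size());
}

// [[Rcpp::export]]
List cpp_emd(NumericVector x, int criterion, double stop_threshold,
             int s_number, int max_siftings, int max_imfs, int boundary) {
  const int n = x.size();
  double ex = 0.0;
  for (int q = 0; q < n; ++q) ex += x[q] * x[q];
  const double tiny = 1e-24 * ex;            // guards machine-epsilon jitter
  std::vector<std::vector<double> > imfs;
  std::vector<double> r(x.begin(), x.end());
  while ((int)imfs.size() < max_imfs) {
    NumericVector rv(r.begin(), r.end());
    std::vector<double> tmax, vmax, tmin, vmin;
    find_extrema_core(rv, tmax, vmax, tmin, vmin);
    if (tmax.empty() || tmin.empty()) break;   // residue: at most one extremum
    std::vector<double> imf; int nsift;
    sift_core(rv, criterion, stop_threshold, s_number, max_siftings,
              boundary, imf, nsift);
    if (nsift == 0) break;
    double ei = 0.0;
    for (int q = 0; q < n; ++q) ei += imf[q] * imf[q];
    if (ei <= tiny) break;                     // nothing extractable remains
    for (int q = 0; q < n; ++q) r[q] -= imf[q];
    imfs.push_back(imf);
  }
  NumericMatrix out(n, (int)imfs.size());
  for (int k = 0; k < (int)imfs.size(); ++k)
    for (int q = 0; q < n; ++q) out(q, k) = imfs[k][q];
  return List::create(_["imfs"] = out,
                      _["residue"] = NumericVector(r.begin(), r.end()));
}
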