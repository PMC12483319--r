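#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with sample
// spacing w. f holds squared distances on input, d the transformed result.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double w2 = w * w;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // infinite parabolas never enter the envelope
    double s = 0.0;
    while (k >= 0) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // whole line infinite
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared EDT of an n-D array: distance from every voxel to the nearest
// reference (TRUE) voxel, with per-axis spacing. Returns +Inf everywhere when
// the reference set is empty.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector ref, IntegerVector dim,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  R_xlen_t total = ref.size();
  NumericVector out(total);
  for (R_xlen_t i = 0; i < total; ++i) out[i] = ref[i] ? 0.0 : INF;
  int nd = dim.size();
  R_xlen_t stride = 1;
  for (int a = 0; a < nd; ++a) {
    int m = dim[a];
    double w = spacing[a];
    R_xlen_t nlines = total / m;
    std::vector<double> f(m), d(m);
    for (R_xlen_t line = 0; line < nlines; ++line) {
      // base index of this line: fold line number around the axis stride
      R_xlen_t lo = line % stride;
      R_xlen_t hi = line / stride;
      R_xlen_t base = lo + hi * stride * m;
      bool any_finite = false;
      for (int k = 0; k < m; ++k) {
        f[k] = out[base + (R_xlen_t)k * stride];
        if (f[k] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f, d, m, w);
      for (int k = 0; k < m; ++k) out[base + (R_xlen_t)k * stride] = d[k];
    }
    stride *= m;
  }
  return out;
}

// Index (1-based, into the flattened array) of the nearest reference voxel is
// not needed by any caller; per-object minima are reduced in R.

// Per-label minimum of a value array: min over voxels of each positive label.
// Returns a matrix with columns (label, min value).
// [[Rcpp::export]]
NumericMatrix label_min_cpp(IntegerVector labels, NumericVector values) {
  std::vector<int> ids;
  std::vector<double> mins;
  std::vector<int> lut;  // label -> slot + 1
  int maxl = 0;
  R_xlen_t n = labels.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] > maxl) maxl = labels[i];
  lut.assign(maxl + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = labels[i];
    if (l <= 0) continue;
    if (lut[l] == 0) {
      ids.push_back(l);
      mins.push_back(values[i]);
      lut[l] = (int)ids.size();
    } else {
      double v = values[i];
      if (v < mins[lut[l] - 1]) mins[lut[l] - 1] = v;
    }
  }
  NumericMatrix res(ids.size(), 2);
  for (size_t k = 0; k < ids.size(); ++k) {
    res(k, 0) = ids[k];
    res(k, 1) = mins[k];
  }
  return res;
}

// Per-label maximum, same layout as label_min_cpp.
// [[Rcpp::export]]
NumericMatrix label_max_cpp(IntegerVector labels, NumericVector values) {
  std::vector<int> ids;
  std::vector<double> maxs;
  std::vector<int> lut;
  int maxl = 0;
  R_xlen_t n = labels.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] > maxl) maxl = labels[i];
  lut.assign(maxl + 1, 0);
  for (R_xlen_t i = 0; i < n; ++i) {
    int l = labels[i];
    if (l <= 0) continue;
    if (lut[l] == 0) {
      ids.push_back(l);
      maxs.push_back(values[i]);
      lut[l] = (int)ids.size();
    } else {
      double v = values[i];
      if (v > maxs[lut[l] - 1]) maxs[lut[l] - 1] = v;
    }
  }
  NumericMatrix res(ids.size(), 2);
  for (size_t k = 0; k < ids.size(); ++k) {
    res(k, 0) = ids[k];
    res(k, 1) = maxs[k];
  }
  return res;
}
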