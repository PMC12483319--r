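#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
#include <map>
using namespace Rcpp;

// Enumerate neighbour offsets for an n-D grid (nd = 2 or 3).
// connectivity: 1 = face neighbours (4 / 6), 2 = full neighbourhood (8 / 26).
static void neighbour_offsets(const IntegerVector& dim, int connectivity,
                              std::vector<std::vector<int>>& offs) {
  int nd = dim.size();
  std::vector<int> delta(nd, -1);
  while (true) {
    int l1 = 0, linf = 0;
    for (int a = 0; a < nd; ++a) {
      l1 += std::abs(delta[a]);
      linf = std::max(linf, std::abs(delta[a]));
    }
    bool keep = (l1 > 0) && (connectivity >= 2 ? linf <= 1 : l1 == 1);
    if (keep) offs.push_back(delta);
    int a = 0;
    while (a < nd && delta[a] == 1) { delta[a] = -1; ++a; }
    if (a == nd) break;
    ++delta[a];
  }
}

static inline void lin_to_coord(R_xlen_t idx, const IntegerVector& dim,
                                std::vector<int>& c) {
  for (int a = 0; a < dim.size(); ++a) {
    c[a] = (int)(idx % dim[a]);
    idx /= dim[a];
  }
}

// Connected component labelling of a binary mask, raster-order label ids
// (deterministic). connectivity: 1 face, 2 full.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  R_xlen_t n = mask.size();
  int nd = dim.size();
  IntegerVector lab(n, 0);
  std::vector<std::vector<int>> offs;
  neighbour_offsets(dim, connectivity, offs);
  std::vector<R_xlen_t> stack;
  std::vector<int> c(nd), cn(nd);
  std::vector<R_xlen_t> strides(nd);
  R_xlen_t s = 1;
  for (int a = 0; a < nd; ++a) { strides[a] = s; s *= dim[a]; }
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      lin_to_coord(p, dim, c);
      for (auto& d : offs) {
        bool ok = true;
        R_xlen_t q = p;
        for (int a = 0; a < nd; ++a) {
          int v = c[a] + d[a];
          if (v < 0 || v >= dim[a]) { ok = false; break; }
          q += (R_xlen_t)d[a] * strides[a];
        }
        if (!ok) continue;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Seeded watershed by priority flood on a heightmap, restricted to a mask.
// Face connectivity; ties broken by insertion order (deterministic raster
// seeding). Voxels outside the mask stay 0.
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector height, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  typedef std::tuple<double, R_xlen_t, R_xlen_t> Node;  // height, counter, idx
  std::priority_queue<Node, std::vector<Node>, std::greater<Node>> pq;
  R_xlen_t n = height.size();
  int nd = dim.size();
  IntegerVector lab(n, 0);
  std::vector<std::vector<int>> offs;
  neighbour_offsets(dim, 1, offs);
  std::vector<R_xlen_t> strides(nd);
  R_xlen_t s = 1;
  for (int a = 0; a < nd; ++a) { strides[a] = s; s *= dim[a]; }
  R_xlen_t counter = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.emplace(height[i], counter++, i);
    }
  }
  std::vector<int> c(nd);
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    R_xlen_t p = std::get<2>(top);
    int l = lab[p];
    lin_to_coord(p, dim, c);
    for (auto& d : offs) {
      bool ok = true;
      R_xlen_t q = p;
      for (int a = 0; a < nd; ++a) {
        int v = c[a] + d[a];
        if (v < 0 || v >= dim[a]) { ok = false; break; }
        q += (R_xlen_t)d[a] * strides[a];
      }
      if (!ok) continue;
      if (mask[q] && lab[q] == 0) {
        lab[q] = l;
        pq.emplace(height[q], counter++, q);
      }
    }
  }
  return lab;
}

// Rim map of an instance labelling: voxels inside an object that have a voxel
// with a different value (background or another id) within Chebyshev radius
// `rim` are marked 1.
// [[Rcpp::export]]
LogicalVector boundary_rim_cpp(IntegerVector labels, IntegerVector dim,
                               int rim) {
  R_xlen_t n = labels.size();
  int nd = dim.size();
  LogicalVector out(n, false);
  std::vector<R_xlen_t> strides(nd);
  R_xlen_t s = 1;
  for (int a = 0; a < nd; ++a) { strides[a] = s; s *= dim[a]; }
  std::vector<int> c(nd);
  // enumerate all offsets within the Chebyshev ball
  std::vector<std::vector<int>> offs;
  std::vector<int> delta(nd, -rim);
  while (true) {
    bool nonzero = false;
    for (int a = 0; a < nd; ++a) if (delta[a] != 0) nonzero = true;
    if (nonzero) offs.push_back(delta);
    int a = 0;
    while (a < nd && delta[a] == rim) { delta[a] = -rim; ++a; }
    if (a == nd) break;
    ++delta[a];
  }
  for (R_xlen_t p = 0; p < n; ++p) {
    int l = labels[p];
    if (l <= 0) continue;
    lin_to_coord(p, dim, c);
    for (auto& d : offs) {
      bool ok = true;
      R_xlen_t q = p;
      for (int a = 0; a < nd; ++a) {
        int v = c[a] + d[a];
        if (v < 0 || v >= dim[a]) { ok = false; break; }
        q += (R_xlen_t)d[a] * strides[a];
      }
      // treat out-of-volume as same-object so image borders are not rims
      if (!ok) continue;
      if (labels[q] != l) { out[p] = true; break; }
    }
  }
  return out;
}

// Overlap table of two instance labellings: rows (id_a, id_b, count) for all
// co-occurring pairs including background (0).
// [[Rcpp::export]]
NumericMatrix overlap_table_cpp(IntegerVector a, IntegerVector b) {
  std::map<std::pair<int, int>, double> tab;
  R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) tab[{a[i], b[i]}] += 1.0;
  NumericMatrix out(tab.size(), 3);
  R_xlen_t r = 0;
  for (auto& kv : tab) {
    out(r, 0) = kv.first.first;
    out(r, 1) = kv.first.second;
    out(r, 2) = kv.second;
    ++r;
  }
  return out;
}
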