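#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian blur with per-axis sigma (in voxels). Replicated edges.
// sigma components of 0 skip the corresponding axis.
// [[Rcpp::export]]
NumericVector gaussian_blur_cpp(NumericVector x, IntegerVector dim,
                                NumericVector sigma) {
  R_xlen_t total = x.size();
  int nd = dim.size();
  std::vector<double> cur(x.begin(), x.end()), nxt(total);
  R_xlen_t stride = 1;
  for (int a = 0; a < nd; ++a) {
    int m = dim[a];
    double sg = sigma[a];
    if (sg > 0) {
      int rad = (int)std::ceil(3.0 * sg);
      std::vector<double> ker(2 * rad + 1);
      double sum = 0.0;
      for (int k = -rad; k <= rad; ++k) {
        ker[k + rad] = std::exp(-0.5 * k * k / (sg * sg));
        sum += ker[k + rad];
      }
      for (auto& v : ker) v /= sum;
      R_xlen_t nlines = total / m;
      for (R_xlen_t line = 0; line < nlines; ++line) {
        R_xlen_t lo = line % stride;
        R_xlen_t hi = line / stride;
        R_xlen_t base = lo + hi * stride * m;
        for (int i = 0; i < m; ++i) {
          double acc = 0.0;
          for (int k = -rad; k <= rad; ++k) {
            int j = i + k;
            if (j < 0) j = 0;
            if (j >= m) j = m - 1;
            acc += ker[k + rad] * cur[base + (R_xlen_t)j * stride];
          }
          nxt[base + (R_xlen_t)i * stride] = acc;
        }
      }
      cur.swap(nxt);
    }
    stride *= m;
  }
  return NumericVector(cur.begin(), cur.end());
}

// Resample an n-D array (nd = 2 or 3) to a new shape. Linear interpolation
// (intensity) or nearest neighbour (labels). Voxel centres are aligned:
// in = (out + 0.5) * n_in / n_out - 0.5 per axis, clamped to the input range.
// [[Rcpp::export]]
NumericVector resample_cpp(NumericVector x, IntegerVector dim,
                           IntegerVector out_dim, bool nearest) {
  int nd = dim.size();
  R_xlen_t out_total = 1;
  for (int a = 0; a < nd; ++a) out_total *= out_dim[a];
  NumericVector out(out_total);
  std::vector<R_xlen_t> strides(nd);
  R_xlen_t s = 1;
  for (int a = 0; a < nd; ++a) { strides[a] = s; s *= dim[a]; }
  std::vector<int> lo(nd), hi(nd), oc(nd);
  std::vector<double> frac(nd);
  for (R_xlen_t p = 0; p < out_total; ++p) {
    R_xlen_t rem = p;
    for (int a = 0; a < nd; ++a) {
      oc[a] = (int)(rem % out_dim[a]);
      rem /= out_dim[a];
      double pos = (oc[a] + 0.5) * (double)dim[a] / (double)out_dim[a] - 0.5;
      if (pos < 0) pos = 0;
      if (pos > dim[a] - 1) pos = dim[a] - 1;
      if (nearest) {
        lo[a] = (int)std::floor(pos + 0.5);
        if (lo[a] > dim[a] - 1) lo[a] = dim[a] - 1;
        hi[a] = lo[a];
        frac[a] = 0.0;
      } else {
        lo[a] = (int)std::floor(pos);
        hi[a] = std::min(lo[a] + 1, dim[a] - 1);
        frac[a] = pos - lo[a];
      }
    }
    // accumulate over the 2^nd interpolation corners
    double acc = 0.0;
    int ncorner = 1 << nd;
    for (int corner = 0; corner < ncorner; ++corner) {
      double wgt = 1.0;
      R_xlen_t idx = 0;
      for (int a = 0; a < nd; ++a) {
        if (corner & (1 << a)) {
          wgt *= frac[a];
          idx += (R_xlen_t)hi[a] * strides[a];
        } else {
          wgt *= (1.0 - frac[a]);
          idx += (R_xlen_t)lo[a] * strides[a];
        }
      }
      if (wgt > 0) acc += wgt * x[idx];
    }
    out[p] = acc;
  }
  return out;
}

// Surface area of an iso-surface through a scalar field, by marching
// tetrahedra (each grid cell split into six tetrahedra sharing the main
// diagonal; crossing vertices linearly interpolated). spacing gives the edge
// lengths per axis; dim is in R array order (first index fastest).
// [[Rcpp::export]]
double mtetra_area_cpp(NumericVector vol, IntegerVector dim, double iso,
                       NumericVector spacing) {
  int nd = dim.size();
  if (nd != 3) stop("mesh surface area requires a 3D array");
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  R_xlen_t s0 = 1, s1 = d0, s2 = (R_xlen_t)d0 * d1;
  // cube corner offsets in (a0, a1, a2) coordinates, corner bit k -> axis k
  static const int corner[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  // six tetrahedra sharing diagonal 0-7
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  double area = 0.0;
  double sp0 = spacing[0], sp1 = spacing[1], sp2 = spacing[2];
  double vals[8];
  double px[4], py[4], pz[4];
  for (int c2 = 0; c2 < d2 - 1; ++c2) {
    for (int c1 = 0; c1 < d1 - 1; ++c1) {
      for (int c0 = 0; c0 < d0 - 1; ++c0) {
        R_xlen_t base = c0 * s0 + (R_xlen_t)c1 * s1 + (R_xlen_t)c2 * s2;
        bool any_above = false, any_below = false;
        for (int k = 0; k < 8; ++k) {
          vals[k] = vol[base + corner[k][0] * s0 + corner[k][1] * s1 +
                        corner[k][2] * s2];
          if (vals[k] > iso) any_above = true; else any_below = true;
        }
        if (!any_above || !any_below) continue;
        for (int t = 0; t < 6; ++t) {
          int above[4], below[4], na = 0, nb = 0;
          for (int k = 0; k < 4; ++k) {
            int v = tets[t][k];
            if (vals[v] > iso) above[na++] = v; else below[nb++] = v;
          }
          if (na == 0 || nb == 0) continue;
          // crossing-edge interpolation points
          int npts = 0;
          int ea[4], eb[4];
          if (na == 1) {
            for (int k = 0; k < 3; ++k) { ea[k] = above[0]; eb[k] = below[k]; }
            npts = 3;
          } else if (na == 3) {
            for (int k = 0; k < 3; ++k) { ea[k] = above[k]; eb[k] = below[0]; }
            npts = 3;
          } else {  // 2-2: quad in cyclic order a0b0, a0b1, a1b1, a1b0
            ea[0] = above[0]; eb[0] = below[0];
            ea[1] = above[0]; eb[1] = below[1];
            ea[2] = above[1]; eb[2] = below[1];
            ea[3] = above[1]; eb[3] = below[0];
            npts = 4;
          }
          for (int k = 0; k < npts; ++k) {
            int va = ea[k], vb = eb[k];
            double tt = (iso - vals[va]) / (vals[vb] - vals[va]);
            px[k] = sp0 * (c0 + corner[va][0] + tt * (corner[vb][0] - corner[va][0]));
            py[k] = sp1 * (c1 + corner[va][1] + tt * (corner[vb][1] - corner[va][1]));
            pz[k] = sp2 * (c2 + corner[va][2] + tt * (corner[vb][2] - corner[va][2]));
          }
          int ntri = npts - 2;
          for (int k = 0; k < ntri; ++k) {
            double ux = px[k + 1] - px[0], uy = py[k + 1] - py[0],
                   uz = pz[k + 1] - pz[0];
            double vx = px[k + 2] - px[0], vy = py[k + 2] - py[0],
                   vz = pz[k + 2] - pz[0];
            double cxp = uy * vz - uz * vy;
            double cyp = uz * vx - ux * vz;
            double czp = ux * vy - uy * vx;
            area += 0.5 * std::sqrt(cxp * cxp + cyp * cyp + czp * czp);
          }
        }
      }
    }
  }
  return area;
}
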