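// Minimal dense building blocks for the UNet: n-D convolution (kernel 1 or
// 3 per axis) as chunked im2col + GEMM, max pooling with per-axis factors,
// and nearest-neighbour upsampling, each with its adjoint for backprop.
// Feature maps are (npix x C) matrices whose rows follow R's array linear
// order over the spatial dimensions.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void kernel_offsets(const IntegerVector& dim, int ksize,
                           std::vector<std::vector<int>>& offs) {
  int nd = dim.size();
  if (ksize == 1) {
    offs.push_back(std::vector<int>(nd, 0));
    return;
  }
  std::vector<int> delta(nd, -1);
  while (true) {
    offs.push_back(delta);
    int a = 0;
    while (a < nd && delta[a] == 1) { delta[a] = -1; ++a; }
    if (a == nd) break;
    ++delta[a];
  }
}

static void strides_of(const IntegerVector& dim, std::vector<R_xlen_t>& st) {
  R_xlen_t s = 1;
  st.resize(dim.size());
  for (int a = 0; a < dim.size(); ++a) { st[a] = s; s *= dim[a]; }
}

// Neighbour table for rows [r0, r1): nbr[j * n + (p - r0)] = source row of
// kernel offset j for output row p, or -1 outside the volume.
static void neighbour_table(const IntegerVector& dim,
                            const std::vector<std::vector<int>>& offs,
                            const std::vector<R_xlen_t>& st, R_xlen_t r0,
                            R_xlen_t r1, std::vector<R_xlen_t>& nbr) {
  int nd = dim.size();
  int K = offs.size();
  R_xlen_t n = r1 - r0;
  nbr.assign((size_t)K * n, -1);
  std::vector<int> c(nd);
  for (R_xlen_t p = r0; p < r1; ++p) {
    R_xlen_t rem = p;
    for (int a = 0; a < nd; ++a) { c[a] = (int)(rem % dim[a]); rem /= dim[a]; }
    for (int j = 0; j < K; ++j) {
      R_xlen_t q = p;
      bool ok = true;
      for (int a = 0; a < nd; ++a) {
        int v = c[a] + offs[j][a];
        if (v < 0 || v >= dim[a]) { ok = false; break; }
        q += (R_xlen_t)offs[j][a] * st[a];
      }
      if (ok) nbr[(size_t)j * n + (p - r0)] = q;
    }
  }
}

// Fill the im2col block for rows [r0, r1) column by column (cache friendly
// for arma's column-major storage).
static void im2col_chunk(const arma::mat& X,
                         const std::vector<R_xlen_t>& nbr, int K,
                         R_xlen_t nrows, arma::mat& M) {
  int Cin = X.n_cols;
  for (int ch = 0; ch < Cin; ++ch) {
    const double* xc = X.colptr(ch);
    for (int j = 0; j < K; ++j) {
      double* mc = M.colptr((size_t)ch * K + j);
      const R_xlen_t* nb = &nbr[(size_t)j * nrows];
      for (R_xlen_t p = 0; p < nrows; ++p) {
        R_xlen_t q = nb[p];
        mc[p] = (q < 0) ? 0.0 : xc[q];
      }
    }
  }
}

static const R_xlen_t CHUNK = 65536;

// [[Rcpp::export]]
arma::mat conv_fw_cpp(const arma::mat& X, IntegerVector dim,
                      const arma::mat& W, const arma::vec& b, int ksize) {
  if (ksize == 1) {
    arma::mat Y = X * W;
    Y.each_row() += b.t();
    return Y;
  }
  std::vector<std::vector<int>> offs;
  kernel_offsets(dim, ksize, offs);
  std::vector<R_xlen_t> st;
  strides_of(dim, st);
  int K = offs.size();
  R_xlen_t n = X.n_rows;
  arma::mat Y(n, W.n_cols);
  std::vector<R_xlen_t> nbr;
  for (R_xlen_t r0 = 0; r0 < n; r0 += CHUNK) {
    R_xlen_t r1 = std::min(r0 + CHUNK, n);
    arma::mat Mc(r1 - r0, W.n_rows);
    neighbour_table(dim, offs, st, r0, r1, nbr);
    im2col_chunk(X, nbr, K, r1 - r0, Mc);
    Y.rows(r0, r1 - 1) = Mc * W;
  }
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List conv_bw_cpp(const arma::mat& X, IntegerVector dim, const arma::mat& W,
                 const arma::mat& dY, int ksize) {
  arma::vec db = arma::sum(dY, 0).t();
  if (ksize == 1) {
    arma::mat dW = X.t() * dY;
    arma::mat dX = dY * W.t();
    return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
  }
  std::vector<std::vector<int>> offs;
  kernel_offsets(dim, ksize, offs);
  std::vector<R_xlen_t> st;
  strides_of(dim, st);
  int K = offs.size();
  int Cin = X.n_cols;
  R_xlen_t n = X.n_rows;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dX(n, Cin, arma::fill::zeros);
  std::vector<R_xlen_t> nbr;
  for (R_xlen_t r0 = 0; r0 < n; r0 += CHUNK) {
    R_xlen_t r1 = std::min(r0 + CHUNK, n);
    R_xlen_t nr = r1 - r0;
    arma::mat Mc(nr, W.n_rows);
    neighbour_table(dim, offs, st, r0, r1, nbr);
    im2col_chunk(X, nbr, K, nr, Mc);
    arma::mat dYc = dY.rows(r0, r1 - 1);
    dW += Mc.t() * dYc;
    arma::mat dG = dYc * W.t();  // (chunk x Cin*K)
    for (int ch = 0; ch < Cin; ++ch) {
      double* dxc = dX.colptr(ch);
      for (int j = 0; j < K; ++j) {
        const double* gc = dG.colptr((size_t)ch * K + j);
        const R_xlen_t* nb = &nbr[(size_t)j * nr];
        for (R_xlen_t p = 0; p < nr; ++p) {
          R_xlen_t q = nb[p];
          if (q >= 0) dxc[q] += gc[p];
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fw_cpp(const arma::mat& X, IntegerVector dim,
                    IntegerVector factors) {
  int nd = dim.size();
  IntegerVector out_dim(nd);
  for (int a = 0; a < nd; ++a) {
    if (dim[a] % factors[a] != 0)
      stop("spatial extent not divisible by pooling factor");
    out_dim[a] = dim[a] / factors[a];
  }
  std::vector<R_xlen_t> st_in, st_out;
  strides_of(dim, st_in);
  strides_of(out_dim, st_out);
  R_xlen_t n_out = 1;
  for (int a = 0; a < nd; ++a) n_out *= out_dim[a];
  int C = X.n_cols;
  arma::mat Y(n_out, C);
  arma::umat idx(n_out, C);
  R_xlen_t nblock = 1;
  for (int a = 0; a < nd; ++a) nblock *= factors[a];
  std::vector<int> oc(nd), bc(nd);
  for (R_xlen_t p = 0; p < n_out; ++p) {
    R_xlen_t rem = p;
    for (int a = 0; a < nd; ++a) { oc[a] = (int)(rem % out_dim[a]); rem /= out_dim[a]; }
    for (int ch = 0; ch < C; ++ch) {
      double best = -arma::datum::inf;
      R_xlen_t bidx = 0;
      for (R_xlen_t blk = 0; blk < nblock; ++blk) {
        R_xlen_t brem = blk;
        R_xlen_t q = 0;
        for (int a = 0; a < nd; ++a) {
          bc[a] = (int)(brem % factors[a]);
          brem /= factors[a];
          q += (R_xlen_t)(oc[a] * factors[a] + bc[a]) * st_in[a];
        }
        double v = X(q, ch);
        if (v > best) { best = v; bidx = q; }
      }
      Y(p, ch) = best;
      idx(p, ch) = bidx;
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx, _["out_dim"] = out_dim);
}

// [[Rcpp::export]]
arma::mat maxpool_bw_cpp(const arma::mat& dY, const arma::umat& idx,
                         R_xlen_t n_in) {
  int C = dY.n_cols;
  arma::mat dX(n_in, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch)
    for (arma::uword p = 0; p < dY.n_rows; ++p)
      dX(idx(p, ch), ch) += dY(p, ch);
  return dX;
}

// [[Rcpp::export]]
arma::mat upsample_fw_cpp(const arma::mat& X, IntegerVector dim,
                          IntegerVector factors) {
  int nd = dim.size();
  IntegerVector out_dim(nd);
  for (int a = 0; a < nd; ++a) out_dim[a] = dim[a] * factors[a];
  std::vector<R_xlen_t> st_in;
  strides_of(dim, st_in);
  R_xlen_t n_out = 1;
  for (int a = 0; a < nd; ++a) n_out *= out_dim[a];
  arma::mat Y(n_out, X.n_cols);
  std::vector<int> oc(nd);
  for (R_xlen_t p = 0; p < n_out; ++p) {
    R_xlen_t rem = p;
    R_xlen_t q = 0;
    for (int a = 0; a < nd; ++a) {
      oc[a] = (int)(rem % out_dim[a]);
      rem /= out_dim[a];
      q += (R_xlen_t)(oc[a] / factors[a]) * st_in[a];
    }
    Y.row(p) = X.row(q);
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat upsample_bw_cpp(const arma::mat& dY, IntegerVector dim_in,
                          IntegerVector factors) {
  int nd = dim_in.size();
  IntegerVector out_dim(nd);
  for (int a = 0; a < nd; ++a) out_dim[a] = dim_in[a] * factors[a];
  std::vector<R_xlen_t> st_in;
  strides_of(dim_in, st_in);
  R_xlen_t n_in = 1;
  for (int a = 0; a < nd; ++a) n_in *= dim_in[a];
  arma::mat dX(n_in, dY.n_cols, arma::fill::zeros);
  std::vector<int> oc(nd);
  R_xlen_t n_out = dY.n_rows;
  for (R_xlen_t p = 0; p < n_out; ++p) {
    R_xlen_t rem = p;
    R_xlen_t q = 0;
    for (int a = 0; a < nd; ++a) {
      oc[a] = (int)(rem % out_dim[a]);
      rem /= out_dim[a];
      q += (R_xlen_t)(oc[a] / factors[a]) * st_in[a];
    }
    dX.row(q) += dY.row(p);
  }
  return dX;
}
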