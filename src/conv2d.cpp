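// Fast im2col-based 2-D convolution kernels for the autodiff engine.
//
// Feature maps are (N*H*W) x C matrices (row = spatial position, column =
// channel; image-major row order). idx is the precomputed gather table:
// idx(r, j) is the 1-based source row of kernel offset j for output position
// r, 0 meaning zero padding. The im2col matrix has column m = j + c*kk for
// kernel offset j (0-based) and input channel c, matching the weight layout
// on the R side.
//
// The computation is blocked per image so the im2col buffer stays
// cache-sized; on a single-core memory-bound host this is several times
// faster than materializing the full batch im2col matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void fill_colm(arma::mat& colm, const double* X, int n_in,
                      const int* idx, int R_total, int off_out,
                      int rows_out, int kk, int Cin) {
  colm.zeros();
  for (int j = 0; j < kk; ++j) {
    const int* src = idx + (std::size_t)j * R_total + off_out;
    for (int c = 0; c < Cin; ++c) {
      const double* xc = X + (std::size_t)c * n_in;
      double* dst = colm.colptr(j + c * kk);
      for (int r = 0; r < rows_out; ++r) {
        if (src[r] > 0) dst[r] = xc[src[r] - 1];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_conv2d_fwd(NumericMatrix Xr, NumericMatrix Wr,
                             IntegerMatrix idxr, int n_img, int rows_out,
                             NumericVector bias) {
  const int kk = idxr.ncol(), Cin = Xr.ncol(), Cout = Wr.ncol();
  const int R_total = idxr.nrow();
  const bool has_b = bias.size() == Cout;
  arma::mat W(Wr.begin(), Wr.nrow(), Cout, false);
  NumericMatrix outr(R_total, Cout);
  arma::mat out(outr.begin(), R_total, Cout, false);
  arma::mat colm(rows_out, kk * Cin);
  for (int im = 0; im < n_img; ++im) {
    const int off = im * rows_out;
    fill_colm(colm, Xr.begin(), Xr.nrow(), idxr.begin(), R_total, off,
              rows_out, kk, Cin);
    arma::mat blk = colm * W;
    if (has_b) {
      for (int c = 0; c < Cout; ++c) blk.col(c) += bias[c];
    }
    out.rows(off, off + rows_out - 1) = blk;
  }
  return outr;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericMatrix Xr, NumericMatrix Wr, NumericMatrix gr,
                    IntegerMatrix idxr, int n_img, int rows_out,
                    bool need_gx) {
  const int kk = idxr.ncol(), Cin = Xr.ncol(), Cout = Wr.ncol();
  const int R_total = idxr.nrow();
  arma::mat W(Wr.begin(), Wr.nrow(), Cout, false);
  arma::mat g(gr.begin(), R_total, Cout, false);
  NumericMatrix gXr(Xr.nrow(), Cin);
  arma::mat gX(gXr.begin(), Xr.nrow(), Cin, false);
  NumericMatrix gWr(Wr.nrow(), Cout);
  arma::mat gW(gWr.begin(), Wr.nrow(), Cout, false);
  arma::mat colm(rows_out, kk * Cin);
  arma::mat gcol(rows_out, kk * Cin);
  for (int im = 0; im < n_img; ++im) {
    const int off = im * rows_out;
    fill_colm(colm, Xr.begin(), Xr.nrow(), idxr.begin(), R_total, off,
              rows_out, kk, Cin);
    const arma::mat gblk = g.rows(off, off + rows_out - 1);
    gW += colm.t() * gblk;
    if (!need_gx) continue;
    gcol = gblk * W.t();
    for (int j = 0; j < kk; ++j) {
      const int* src = idxr.begin() + (std::size_t)j * R_total + off;
      for (int c = 0; c < Cin; ++c) {
        double* dst = gX.colptr(c);
        const double* gc = gcol.colptr(j + c * kk);
        for (int r = 0; r < rows_out; ++r) {
          if (src[r] > 0) dst[src[r] - 1] += gc[r];
        }
      }
    }
  }
  return List::create(Named("gX") = gXr, Named("gW") = gWr);
}

// row-broadcast helpers: out = X op v (v recycled along columns)
// [[Rcpp::export]]
NumericMatrix cpp_add_rowvec(NumericMatrix Xr, NumericVector v) {
  const int n = Xr.nrow(), C = Xr.ncol();
  NumericMatrix outr(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = Xr.begin() + (std::size_t)c * n;
    double* oc = outr.begin() + (std::size_t)c * n;
    const double vc = v[c];
    for (int r = 0; r < n; ++r) oc[r] = xc[r] + vc;
  }
  return outr;
}

// [[Rcpp::export]]
NumericMatrix cpp_mul_rowvec(NumericMatrix Xr, NumericVector v) {
  const int n = Xr.nrow(), C = Xr.ncol();
  NumericMatrix outr(n, C);
  for (int c = 0; c < C; ++c) {
    const double* xc = Xr.begin() + (std::size_t)c * n;
    double* oc = outr.begin() + (std::size_t)c * n;
    const double vc = v[c];
    for (int r = 0; r < n; ++r) oc[r] = xc[r] * vc;
  }
  return outr;
}
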