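// 3x3x3 stride-1 zero-padded 3D convolution, forward and backward, via
// im2col and BLAS matrix products. Volumes are column-major (x fastest)
// with channels last, matching R arrays of dim (d1, d2, d3, C).
//
// Weight layout for a layer with Cin inputs and Cout outputs: a
// (27*Cin) x Cout matrix whose row index is offset + 27*channel, with the
// kernel offset enumerated x-fastest (a + 3*b + 9*c for shifts a,b,c in
// 0..2 relative to -1). The input gradient is a convolution of the output
// gradient with the spatially flipped, transposed kernel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col3(const double* x, const int* d, const int C) {
  const int d1 = d[0], d2 = d[1], d3 = d[2];
  const arma::uword nvox = (arma::uword)d1 * d2 * d3;
  arma::mat X(nvox, 27 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (arma::uword)c * nvox;
    const int col0 = c * 27;
    for (int cc = 0; cc < 3; ++cc) {
      for (int b = 0; b < 3; ++b) {
        for (int a = 0; a < 3; ++a) {
          const int dz = cc - 1, dyy = b - 1, dxx = a - 1;
          double* Xcol = X.colptr(col0 + 9 * cc + 3 * b + a);
          const int i0 = std::max(0, -dxx);
          const int i1 = std::min(d1, d1 - dxx);
          if (i1 <= i0) continue;
          for (int k = 0; k < d3; ++k) {
            const int kk = k + dz;
            if (kk < 0 || kk >= d3) continue;
            for (int j = 0; j < d2; ++j) {
              const int jj = j + dyy;
              if (jj < 0 || jj >= d2) continue;
              const double* src = xc + ((arma::uword)kk * d2 + jj) * d1 + (i0 + dxx);
              double* dst = Xcol + ((arma::uword)k * d2 + j) * d1 + i0;
              std::copy(src, src + (i1 - i0), dst);
            }
          }
        }
      }
    }
  }
  return X;
}

// [[Rcpp::export]]
arma::mat conv3d_forward_cpp(const NumericVector& x, const IntegerVector& dim,
                             const int cin, const arma::mat& W,
                             const arma::vec& b) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  arma::mat X = im2col3(x.begin(), d, cin);
  arma::mat Y = X * W;
  Y.each_row() += b.t();
  return Y;
}

// [[Rcpp::export]]
List conv3d_backward_cpp(const NumericVector& x, const IntegerVector& dim,
                         const int cin, const arma::mat& dy,
                         const arma::mat& W, const bool need_dx) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int cout = dy.n_cols;
  arma::mat X = im2col3(x.begin(), d, cin);
  arma::mat dW = X.t() * dy;
  arma::rowvec db = arma::sum(dy, 0);
  if (!need_dx) {
    return List::create(_["dW"] = dW, _["db"] = db);
  }
  arma::mat Wf(27 * cout, cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int co = 0; co < cout; ++co)
      for (int o = 0; o < 27; ++o)
        Wf((arma::uword)co * 27 + o, ci) = W((arma::uword)ci * 27 + (26 - o), co);
  arma::mat Xy = im2col3(dy.memptr(), d, cout);
  arma::mat dx = Xy * Wf;
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
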