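// Batched 2-D convolution forward/backward via im2col + BLAS gemm.
//
// Tensor layout: a batch of n feature maps of spatial size H x W with C
// channels is an n x (H*W*C) matrix; within a row the (h, w, c) element
// sits at index (h-1) + (w-1)*H + (c-1)*H*W (column-major spatial, channel
// slowest). The index map `idx` (length P*KKC, 0-based, -1 = zero padding)
// is precomputed in R for the layer geometry: entry [p + P*j] gives the
// source column of patch element j at output position p.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_col(const arma::mat& X, const IntegerVector& idx,
                           int P, int KKC) {
  const arma::uword n = X.n_rows;
  arma::mat col(n * P, KKC);
  for (int j = 0; j < KKC; ++j) {
    double* dst = col.colptr(j);
    for (int p = 0; p < P; ++p) {
      const int src = idx[p + P * j];
      if (src < 0) {
        std::memset(dst + p * n, 0, n * sizeof(double));
      } else {
        std::memcpy(dst + p * n, X.colptr(src), n * sizeof(double));
      }
    }
  }
  return col;
}

// Forward pass. X: n x (H*W*Cin); W: KKC x F; b: length F.
// Returns n x (P*F): output position fastest, filter slowest, i.e. the same
// layout contract with F output channels.
// [[Rcpp::export]]
arma::mat nn_conv_fwd(const arma::mat& X, const IntegerVector& idx,
                      const int P, const arma::mat& W, const arma::vec& b) {
  const int KKC = W.n_rows;
  const arma::uword n = X.n_rows;
  arma::mat out = build_col(X, idx, P, KKC) * W; // (n*P) x F
  for (arma::uword f = 0; f < W.n_cols; ++f) out.col(f) += b[f];
  out.reshape(n, P * W.n_cols); // same memory order, reinterpreted
  return out;
}

// Backward pass. dOut: n x (P*F) in the forward output layout.
// Returns gradients w.r.t. the input map, the kernel matrix and the bias.
// [[Rcpp::export]]
List nn_conv_bwd(const arma::mat& X, const IntegerVector& idx, const int P,
                 const arma::mat& W, const arma::mat& dOut) {
  const int KKC = W.n_rows;
  const int F = W.n_cols;
  const arma::uword n = X.n_rows;
  arma::mat col = build_col(X, idx, P, KKC);
  arma::mat dOutM(const_cast<double*>(dOut.memptr()), n * P, F, false, true);
  arma::mat dW = col.t() * dOutM;
  arma::vec db = arma::sum(dOutM, 0).t();
  arma::mat dcol = dOutM * W.t(); // (n*P) x KKC
  arma::mat dX(n, X.n_cols, arma::fill::zeros);
  for (int j = 0; j < KKC; ++j) {
    const double* src = dcol.colptr(j);
    for (int p = 0; p < P; ++p) {
      const int tgt = idx[p + P * j];
      if (tgt < 0) continue;
      double* dst = dX.colptr(tgt);
      const double* s = src + p * n;
      for (arma::uword i = 0; i < n; ++i) dst[i] += s[i];
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW, Named("db") = db);
}
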