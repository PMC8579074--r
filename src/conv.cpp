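// Convolution layers as per-sample im2col + small GEMMs.
//
// Data layout (matches the R side): a sample image with C channels is a
// column vector over (h, w, c), h fastest; a batch is a D x B matrix.
// The gather plan `idx` (1-based, over the padded image plus one phantom
// zero cell at the end) and the original-cell positions `origPos` are
// built once per layer shape in R (.convPlan).  Working per sample keeps
// the gathered KKC x P column matrix in cache, which is what makes this
// faster than one huge batched GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".convForwardCpp")]]
arma::mat convForwardCpp(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, const arma::uvec& idx,
                         const arma::uvec& origPos, int Dp, int P) {
  const uword B = X.n_cols;
  const uword F = W.n_rows;
  const uword KKC = W.n_cols;
  const uword nIdx = idx.n_elem;
  mat out(static_cast<uword>(P) * F, B);
  vec xp(static_cast<uword>(Dp) + 1, fill::zeros);
  mat cols(KKC, static_cast<uword>(P));
  for (uword j = 0; j < B; ++j) {
    const double* xj = X.colptr(j);
    double* xpm = xp.memptr();
    const uword* op = origPos.memptr();
    for (uword i = 0; i < origPos.n_elem; ++i) xpm[op[i] - 1] = xj[i];
    double* cm = cols.memptr();
    const uword* im = idx.memptr();
    for (uword i = 0; i < nIdx; ++i) cm[i] = xpm[im[i] - 1];
    mat Z = W * cols;               // F x P
    Z.each_col() += b;
    double* oj = out.colptr(j);
    for (uword p = 0; p < static_cast<uword>(P); ++p)
      for (uword f = 0; f < F; ++f)
        oj[p + f * static_cast<uword>(P)] = Z.at(f, p);
  }
  return out;
}

// [[Rcpp::export(name = ".convBackwardCpp")]]
Rcpp::List convBackwardCpp(const arma::mat& X, const arma::mat& W,
                           const arma::uvec& idx, const arma::uvec& origPos,
                           int Dp, int P, const arma::mat& dOut,
                           bool needDx) {
  const uword B = X.n_cols;
  const uword F = W.n_rows;
  const uword KKC = W.n_cols;
  const uword nIdx = idx.n_elem;
  mat dW(F, KKC, fill::zeros);
  vec db(F, fill::zeros);
  mat dX;
  if (needDx) dX.zeros(X.n_rows, B);
  vec xp(static_cast<uword>(Dp) + 1, fill::zeros);
  vec dxp(static_cast<uword>(Dp) + 1);
  mat cols(KKC, static_cast<uword>(P));
  mat dZ(F, static_cast<uword>(P));
  for (uword j = 0; j < B; ++j) {
    const double* xj = X.colptr(j);
    double* xpm = xp.memptr();
    const uword* op = origPos.memptr();
    for (uword i = 0; i < origPos.n_elem; ++i) xpm[op[i] - 1] = xj[i];
    double* cm = cols.memptr();
    const uword* im = idx.memptr();
    for (uword i = 0; i < nIdx; ++i) cm[i] = xpm[im[i] - 1];
    const double* dj = dOut.colptr(j);
    for (uword p = 0; p < static_cast<uword>(P); ++p)
      for (uword f = 0; f < F; ++f)
        dZ.at(f, p) = dj[p + f * static_cast<uword>(P)];
    dW += dZ * cols.t();
    db += sum(dZ, 1);
    if (needDx) {
      mat dCols = W.t() * dZ;       // KKC x P
      dxp.zeros();
      double* dxm = dxp.memptr();
      const double* dcm = dCols.memptr();
      for (uword i = 0; i < nIdx; ++i) dxm[im[i] - 1] += dcm[i];
      double* dXj = dX.colptr(j);
      for (uword i = 0; i < origPos.n_elem; ++i) dXj[i] = dxm[op[i] - 1];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db,
                            Rcpp::Named("dX") = dX);
}
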