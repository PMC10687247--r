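// Minimal conv-net primitives (3x3 'same' convolution, 2x2 max pool) used by
// the small spectrogram classifier. Weight layout: W is (9*Cin) x Cout with
// row index k = (ci * 9 + dy * 3 + dx), dy/dx in {0,1,2}.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static cube pad1(const cube& X) {
  cube P(X.n_rows + 2, X.n_cols + 2, X.n_slices, fill::zeros);
  P.subcube(1, 1, 0, X.n_rows, X.n_cols, X.n_slices - 1) = X;
  return P;
}

// [[Rcpp::export]]
arma::cube cs_conv_fw(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b) {
  const uword H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices,
              Cout = W.n_cols;
  cube P = pad1(X);
  cube Y(H, Wd, Cout);
  for (uword co = 0; co < Cout; ++co) {
    mat acc(H, Wd, fill::value(b(co)));
    for (uword ci = 0; ci < Cin; ++ci)
      for (uword dy = 0; dy < 3; ++dy)
        for (uword dx = 0; dx < 3; ++dx) {
          double w = W(ci * 9 + dy * 3 + dx, co);
          if (w != 0.0)
            acc += w * P.slice(ci).submat(dy, dx, dy + H - 1, dx + Wd - 1);
        }
    Y.slice(co) = acc;
  }
  return Y;
}

// [[Rcpp::export]]
Rcpp::List cs_conv_bw(const arma::cube& X, const arma::mat& W,
                      const arma::cube& dY) {
  const uword H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices,
              Cout = W.n_cols;
  cube P = pad1(X);
  cube dP(H + 2, Wd + 2, Cin, fill::zeros);
  mat dW(W.n_rows, W.n_cols, fill::zeros);
  vec db(Cout, fill::zeros);
  for (uword co = 0; co < Cout; ++co) {
    const mat& g = dY.slice(co);
    db(co) = accu(g);
    for (uword ci = 0; ci < Cin; ++ci)
      for (uword dy = 0; dy < 3; ++dy)
        for (uword dx = 0; dx < 3; ++dx) {
          uword k = ci * 9 + dy * 3 + dx;
          dW(k, co) += accu(
            P.slice(ci).submat(dy, dx, dy + H - 1, dx + Wd - 1) % g);
          dP.slice(ci).submat(dy, dx, dy + H - 1, dx + Wd - 1) += W(k, co) * g;
        }
  }
  cube dX = dP.subcube(1, 1, 0, H, Wd, Cin - 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
Rcpp::List cs_pool_fw(const arma::cube& X) {
  const uword H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube Y(H, W, C);
  ucube idx(H, W, C);   // linear index into the input slice
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        uword bi = 2 * i, bj = 2 * j, best_i = bi, best_j = bj;
        double best = X(bi, bj, c);
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di)
            if (X(bi + di, bj + dj, c) > best) {
              best = X(bi + di, bj + dj, c);
              best_i = bi + di; best_j = bj + dj;
            }
        Y(i, j, c) = best;
        idx(i, j, c) = best_j * X.n_rows + best_i;
      }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cs_pool_bw(const arma::cube& dY, const arma::ucube& idx,
                      int H, int W) {
  const uword C = dY.n_slices;
  cube dX(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    double* sl = dX.slice_memptr(c);
    for (uword j = 0; j < dY.n_cols; ++j)
      for (uword i = 0; i < dY.n_rows; ++i)
        sl[idx(i, j, c)] += dY(i, j, c);
  }
  return dX;
}
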