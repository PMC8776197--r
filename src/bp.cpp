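// Back-propagation neural network: single tanh hidden layer, softmax
// output, cross-entropy loss, full-batch gradient descent with momentum,
// early stopping on a held-out validation split. Weights are initialised
// from R's RNG so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat softmax_rows(arma::mat Z) {
  Z.each_col() -= arma::max(Z, 1);
  Z = arma::exp(Z);
  Z.each_col() /= arma::sum(Z, 1);
  return Z;
}

// [[Rcpp::export(name = ".bp_fit_predict")]]
IntegerVector bp_fit_predict(const arma::mat& Xtr, const IntegerVector& ytr,
                             const arma::mat& Xval,
                             const IntegerVector& yval,
                             const arma::mat& Xte, int n_classes,
                             int size, double lr, double momentum,
                             int max_epochs, int check, int patience) {
  const int n = Xtr.n_rows, d = Xtr.n_cols, K = n_classes;
  arma::mat Y(n, K, arma::fill::zeros);
  for (int i = 0; i < n; ++i) Y(i, ytr[i]) = 1.0;

  // R-RNG-seeded initialisation (caller does set.seed)
  arma::mat W1(d, size), W2(size, K);
  for (auto& v : W1) v = R::rnorm(0.0, 1.0 / std::sqrt((double)d));
  for (auto& v : W2) v = R::rnorm(0.0, 1.0 / std::sqrt((double)size));
  arma::rowvec b1(size, arma::fill::zeros), b2(K, arma::fill::zeros);
  arma::mat vW1(d, size, arma::fill::zeros), vW2(size, K, arma::fill::zeros);
  arma::rowvec vb1(size, arma::fill::zeros), vb2(K, arma::fill::zeros);

  arma::mat bW1 = W1, bW2 = W2;
  arma::rowvec bb1 = b1, bb2 = b2;
  double best_acc = -1.0;
  int wait = 0;

  for (int ep = 1; ep <= max_epochs; ++ep) {
    arma::mat H = Xtr * W1;
    H.each_row() += b1;
    H = arma::tanh(H);
    arma::mat Z = H * W2;
    Z.each_row() += b2;
    arma::mat P = softmax_rows(Z);
    arma::mat dZ = (P - Y) / n;
    arma::mat gW2 = H.t() * dZ;
    arma::rowvec gb2 = arma::sum(dZ, 0);
    arma::mat dH = (dZ * W2.t()) % (1.0 - H % H);
    arma::mat gW1 = Xtr.t() * dH;
    arma::rowvec gb1 = arma::sum(dH, 0);
    vW1 = momentum * vW1 - lr * gW1; W1 += vW1;
    vb1 = momentum * vb1 - lr * gb1; b1 += vb1;
    vW2 = momentum * vW2 - lr * gW2; W2 += vW2;
    vb2 = momentum * vb2 - lr * gb2; b2 += vb2;

    if (ep % check == 0 || ep == max_epochs) {
      arma::mat Hv = Xval * W1;
      Hv.each_row() += b1;
      Hv = arma::tanh(Hv);
      arma::mat Zv = Hv * W2;
      Zv.each_row() += b2;
      arma::uvec pred = arma::index_max(Zv, 1);
      int hits = 0;
      for (arma::uword i = 0; i < pred.n_elem; ++i)
        if ((int)pred[i] == yval[i]) ++hits;
      double acc = (double)hits / pred.n_elem;
      if (acc > best_acc + 1e-9) {
        best_acc = acc;
        bW1 = W1; bb1 = b1; bW2 = W2; bb2 = b2;
        wait = 0;
      } else if (++wait >= patience) break;
    }
  }

  arma::mat Ht = Xte * bW1;
  Ht.each_row() += bb1;
  Ht = arma::tanh(Ht);
  arma::mat Zt = Ht * bW2;
  Zt.each_row() += bb2;
  arma::uvec pred = arma::index_max(Zt, 1);
  IntegerVector out(pred.n_elem);
  for (arma::uword i = 0; i < pred.n_elem; ++i) out[i] = (int)pred[i];
  return out;
}
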