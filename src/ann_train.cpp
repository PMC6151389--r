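// Online back-propagation with momentum for the one-hidden-layer sigmoid
// network. The per-example update loop lives here for speed; the R-level
// annBackpropStep() is the reference implementation and the two are pinned
// against each other in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

static double batch_loss(const mat& X, const mat& Y, const mat& M,
                         const mat& W1, const vec& b1, const mat& W2,
                         const vec& b2, bool xent) {
  mat H = sigm(X * W1.t() + repmat(b1.t(), X.n_rows, 1));
  mat P = sigm(H * W2.t() + repmat(b2.t(), X.n_rows, 1));
  if (xent) {
    mat L = -(Y % log(P + 1e-12) + (1.0 - Y) % log(1.0 - P + 1e-12));
    if (M.n_rows == Y.n_rows) L %= M;
    return accu(L);
  }
  mat E = P - Y;
  if (M.n_rows == Y.n_rows) E %= M;
  return 0.5 * accu(E % E);
}

// [[Rcpp::export(name = ".annTrainCpp")]]
Rcpp::List ann_train_cpp(arma::mat W1, arma::vec b1, arma::mat W2,
                         arma::vec b2, arma::mat vW1, arma::vec vb1,
                         arma::mat vW2, arma::vec vb2, const arma::mat& X,
                         const arma::mat& Y, const arma::mat& mask,
                         const arma::imat& orders, double eta, double alpha,
                         bool xent, const arma::mat& Xval,
                         const arma::mat& Yval, int patience) {
  const int epochs = orders.n_rows;
  const bool hasMask = mask.n_rows == Y.n_rows;
  const bool hasVal = Xval.n_rows > 0;
  std::vector<double> trace, valTrace;
  trace.reserve(epochs);
  double bestVal = datum::inf;
  int bestEpoch = 0, sinceBest = 0, ran = 0;
  mat bW1 = W1, bW2 = W2;
  vec bb1 = b1, bb2 = b2;
  mat bvW1 = vW1, bvW2 = vW2;
  vec bvb1 = vb1, bvb2 = vb2;
  mat dummy(0, 0);

  for (int ep = 0; ep < epochs; ++ep) {
    for (unsigned int k = 0; k < orders.n_cols; ++k) {
      const int i = orders(ep, k) - 1;
      vec x = X.row(i).t();
      vec t = Y.row(i).t();
      vec h = sigm(W1 * x + b1);
      vec y = sigm(W2 * h + b2);
      vec dOut = y - t;
      if (!xent) dOut %= y % (1.0 - y);
      if (hasMask) dOut %= mask.row(i).t();
      vec dHid = (W2.t() * dOut) % h % (1.0 - h);
      vW2 = -eta * dOut * h.t() + alpha * vW2;
      vb2 = -eta * dOut + alpha * vb2;
      vW1 = -eta * dHid * x.t() + alpha * vW1;
      vb1 = -eta * dHid + alpha * vb1;
      W2 += vW2; b2 += vb2;
      W1 += vW1; b1 += vb1;
    }
    ran = ep + 1;
    trace.push_back(batch_loss(X, Y, hasMask ? mask : dummy, W1, b1, W2,
                               b2, xent));
    if (hasVal) {
      double vl = batch_loss(Xval, Yval, dummy, W1, b1, W2, b2, xent);
      valTrace.push_back(vl);
      if (vl < bestVal) {
        bestVal = vl;
        bestEpoch = ran;
        sinceBest = 0;
        bW1 = W1; bb1 = b1; bW2 = W2; bb2 = b2;
        bvW1 = vW1; bvb1 = vb1; bvW2 = vW2; bvb2 = vb2;
      } else if (++sinceBest >= patience) {
        break;
      }
    }
  }
  if (!hasVal) {
    bW1 = W1; bb1 = b1; bW2 = W2; bb2 = b2;
    bvW1 = vW1; bvb1 = vb1; bvW2 = vW2; bvb2 = vb2;
    bestEpoch = ran;
  }
  return Rcpp::List::create(
      Rcpp::Named("W1") = bW1, Rcpp::Named("b1") = bb1,
      Rcpp::Named("W2") = bW2, Rcpp::Named("b2") = bb2,
      Rcpp::Named("vW1") = bvW1, Rcpp::Named("vb1") = bvb1,
      Rcpp::Named("vW2") = bvW2, Rcpp::Named("vb2") = bvb2,
      Rcpp::Named("trace") = trace, Rcpp::Named("valTrace") = valTrace,
      Rcpp::Named("bestEpoch") = bestEpoch,
      Rcpp::Named("epochsRun") = ran);
}
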