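// Tanh (Elman) recurrence used by both modality encoders.  The time loop is
// the only part of the model hot enough to need compiled code; everything
// else (convolutions, attention, classifier head) is plain matrix algebra
// and stays in R.  Internally the sequence is held column-wise (d x T) so
// each step touches contiguous memory.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// h_t = tanh(x_t Wx + h_{t-1} Wh + b), h_0 = 0.
// X: T x d_in, Wx: d_in x h, Wh: h x h, b: h.  Returns H: T x h.
// [[Rcpp::export(name = ".rnn_forward_cpp")]]
arma::mat rnn_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                          const arma::mat& Wh, const arma::vec& b) {
  const arma::uword T = X.n_rows, h = Wx.n_cols;
  const arma::mat Xt = X.t();           // d_in x T
  const arma::mat Wxt = Wx.t();         // h x d_in
  const arma::mat Wht = Wh.t();         // h x h
  arma::mat Ht(h, T);
  arma::vec hprev(h, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t) {
    hprev = arma::tanh(Wxt * Xt.col(t) + Wht * hprev + b);
    Ht.col(t) = hprev;
  }
  return Ht.t();
}

// Backpropagation through time for the recurrence above.
// dH: T x h upstream gradient.  Returns gradients for Wx, Wh, b and X.
// [[Rcpp::export(name = ".rnn_backward_cpp")]]
List rnn_backward_cpp(const arma::mat& X, const arma::mat& H,
                      const arma::mat& Wx, const arma::mat& Wh,
                      const arma::mat& dH) {
  const arma::uword T = X.n_rows, h = Wx.n_cols;
  const arma::mat Xt = X.t();           // d_in x T
  const arma::mat Ht = H.t();           // h x T
  const arma::mat dHt = dH.t();         // h x T
  arma::mat dWx(arma::size(Wx), arma::fill::zeros);
  arma::mat dWh(arma::size(Wh), arma::fill::zeros);
  arma::vec db(h, arma::fill::zeros);
  arma::mat dXt(arma::size(Xt), arma::fill::zeros);
  arma::vec carry(h, arma::fill::zeros);
  for (arma::uword tt = T; tt-- > 0;) {
    // d/da tanh(a) = 1 - tanh(a)^2, tanh(a) = Ht.col(tt)
    const arma::vec da = (dHt.col(tt) + carry) %
      (1.0 - arma::square(Ht.col(tt)));
    dWx += Xt.col(tt) * da.t();
    if (tt > 0) dWh += Ht.col(tt - 1) * da.t();
    db += da;
    dXt.col(tt) = Wx * da;
    carry = Wh * da;
  }
  return List::create(Named("dWx") = dWx, Named("dWh") = dWh,
                      Named("db") = db, Named("dX") = dXt.t());
}
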