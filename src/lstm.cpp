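// LSTM cell forward/backward over a sequence. Hidden/cell states start at
// zero. Gate stacking order in the weight matrices is [input; forget;
// cell-candidate; output], each block of `dh` rows.
//
// Shapes: X is d_in x T (one column per timestep), Wx is 4dh x d_in,
// Wh is 4dh x dh, b is 4dh. The backward pass consumes the activations
// cached by the forward pass and the gradient dH (dh x T) of the loss
// with respect to every hidden state.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List lstm_forward_cpp(const arma::mat& X, const arma::mat& Wx,
                            const arma::mat& Wh, const arma::vec& b) {
  const uword T = X.n_cols;
  const uword dh = Wh.n_cols;
  mat H(dh, T, fill::zeros), C(dh, T, fill::zeros);
  mat I(dh, T), F(dh, T), G(dh, T), O(dh, T);
  vec h_prev(dh, fill::zeros), c_prev(dh, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    vec z = Wx * X.col(t) + Wh * h_prev + b;
    vec i = 1.0 / (1.0 + exp(-z.rows(0, dh - 1)));
    vec f = 1.0 / (1.0 + exp(-z.rows(dh, 2 * dh - 1)));
    vec g = tanh(z.rows(2 * dh, 3 * dh - 1));
    vec o = 1.0 / (1.0 + exp(-z.rows(3 * dh, 4 * dh - 1)));
    vec c = f % c_prev + i % g;
    vec h = o % tanh(c);
    I.col(t) = i; F.col(t) = f; G.col(t) = g; O.col(t) = o;
    C.col(t) = c; H.col(t) = h;
    h_prev = h; c_prev = c;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("C") = C,
                            Rcpp::Named("I") = I, Rcpp::Named("F") = F,
                            Rcpp::Named("G") = G, Rcpp::Named("O") = O);
}

// [[Rcpp::export]]
Rcpp::List lstm_backward_cpp(const arma::mat& X, const arma::mat& Wx,
                             const arma::mat& Wh, const Rcpp::List& cache,
                             const arma::mat& dH) {
  const mat H = cache["H"], C = cache["C"];
  const mat I = cache["I"], F = cache["F"], G = cache["G"], O = cache["O"];
  const uword T = X.n_cols;
  const uword dh = Wh.n_cols;
  mat dX(X.n_rows, T, fill::zeros);
  mat dWx(size(Wx), fill::zeros), dWh(size(Wh), fill::zeros);
  vec db(4 * dh, fill::zeros);
  vec dh_next(dh, fill::zeros), dc_next(dh, fill::zeros);
  for (uword t = T; t-- > 0;) {
    vec dht = dH.col(t) + dh_next;
    vec tc = tanh(C.col(t));
    vec dot = dht % tc;
    vec dc = dht % O.col(t) % (1.0 - tc % tc) + dc_next;
    vec c_prev = (t == 0) ? vec(dh, fill::zeros) : vec(C.col(t - 1));
    vec h_prev = (t == 0) ? vec(dh, fill::zeros) : vec(H.col(t - 1));
    vec di = dc % G.col(t);
    vec df = dc % c_prev;
    vec dg = dc % I.col(t);
    dc_next = dc % F.col(t);
    vec dz(4 * dh);
    dz.rows(0, dh - 1)          = di % I.col(t) % (1.0 - I.col(t));
    dz.rows(dh, 2 * dh - 1)     = df % F.col(t) % (1.0 - F.col(t));
    dz.rows(2 * dh, 3 * dh - 1) = dg % (1.0 - G.col(t) % G.col(t));
    dz.rows(3 * dh, 4 * dh - 1) = dot % O.col(t) % (1.0 - O.col(t));
    dWx += dz * X.col(t).t();
    dWh += dz * h_prev.t();
    db += dz;
    dX.col(t) = Wx.t() * dz;
    dh_next = Wh.t() * dz;
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dWx") = dWx,
                            Rcpp::Named("dWh") = dWh, Rcpp::Named("db") = db);
}
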