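// Bidirectional LSTM building blocks for the sequence tagger.
//
// Parameter layout: a single-direction LSTM over inputs of dimension D with
// hidden size H is one weight matrix W of shape (4H) x (D + H + 1); the last
// column is the bias.  Row blocks are the input (i), forget (f), output (o)
// and candidate (g) gates, in that order.  Backward passes are hand-derived
// and verified against numeric gradients in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec sigm(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

// Forward pass over a full sequence. X is D x L (one column per timestep).
// Returns hidden states h (H x L) plus the caches needed by the backward
// pass: cell states c (H x L) and gate activations (4H x L).
// [[Rcpp::export]]
Rcpp::List cpp_lstm_forward(const arma::mat& X, const arma::mat& W) {
  const uword D = X.n_rows, L = X.n_cols;
  const uword H = W.n_rows / 4;
  if (W.n_cols != D + H + 1)
    Rcpp::stop("lstm weight matrix has %d columns, expected %d",
               (int)W.n_cols, (int)(D + H + 1));
  mat h(H, L, fill::zeros), c(H, L, fill::zeros), gates(4 * H, L, fill::zeros);
  vec hprev(H, fill::zeros), cprev(H, fill::zeros);
  for (uword t = 0; t < L; ++t) {
    vec input = join_cols(join_cols(X.col(t), hprev), vec{1.0});
    vec z = W * input;
    vec gi = sigm(z.subvec(0, H - 1));
    vec gf = sigm(z.subvec(H, 2 * H - 1));
    vec go = sigm(z.subvec(2 * H, 3 * H - 1));
    vec gg = tanh(z.subvec(3 * H, 4 * H - 1));
    vec ct = gf % cprev + gi % gg;
    vec ht = go % tanh(ct);
    gates.col(t) = join_cols(join_cols(gi, gf), join_cols(go, gg));
    c.col(t) = ct;
    h.col(t) = ht;
    hprev = ht;
    cprev = ct;
  }
  return Rcpp::List::create(Rcpp::Named("h") = h,
                            Rcpp::Named("c") = c,
                            Rcpp::Named("gates") = gates);
}

// Backward pass. dh is the upstream gradient on every hidden state (H x L;
// zero columns where a state is unused, e.g. the character encoder only
// consumes the final state).  Returns gradients on the inputs and on W.
// [[Rcpp::export]]
Rcpp::List cpp_lstm_backward(const arma::mat& X, const arma::mat& W,
                             const arma::mat& h, const arma::mat& c,
                             const arma::mat& gates, const arma::mat& dh_up) {
  const uword D = X.n_rows, L = X.n_cols;
  const uword H = W.n_rows / 4;
  mat dX(D, L, fill::zeros), dW(size(W), fill::zeros);
  vec dh_next(H, fill::zeros), dc_next(H, fill::zeros);
  for (uword tt = L; tt-- > 0;) {
    vec gi = gates.col(tt).subvec(0, H - 1);
    vec gf = gates.col(tt).subvec(H, 2 * H - 1);
    vec go = gates.col(tt).subvec(2 * H, 3 * H - 1);
    vec gg = gates.col(tt).subvec(3 * H, 4 * H - 1);
    vec ct = c.col(tt);
    vec cprev = (tt == 0) ? vec(H, fill::zeros) : vec(c.col(tt - 1));
    vec hprev = (tt == 0) ? vec(H, fill::zeros) : vec(h.col(tt - 1));
    vec tc = tanh(ct);

    vec dht = dh_up.col(tt) + dh_next;
    vec dgo = dht % tc;
    vec dct = dht % go % (1.0 - tc % tc) + dc_next;
    vec dgi = dct % gg;
    vec dgf = dct % cprev;
    vec dgg = dct % gi;
    dc_next = dct % gf;

    vec dz = join_cols(join_cols(dgi % gi % (1.0 - gi),
                                 dgf % gf % (1.0 - gf)),
                       join_cols(dgo % go % (1.0 - go),
                                 dgg % (1.0 - gg % gg)));
    vec input = join_cols(join_cols(X.col(tt), hprev), vec{1.0});
    dW += dz * input.t();
    vec dinput = W.t() * dz;
    dX.col(tt) = dinput.subvec(0, D - 1);
    dh_next = dinput.subvec(D, D + H - 1);
  }
  return Rcpp::List::create(Rcpp::Named("dX") = dX,
                            Rcpp::Named("dW") = dW);
}

// Character encoder: for each token, run a bidirectional LSTM over its
// character embeddings and concatenate the two final hidden states.
// char_ids: list of 1-based integer vectors (rows of emb); emb: C x char_dim.
// Returns feats (2H x n_tokens) and per-token caches for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_char_encode(const Rcpp::List& char_ids, const arma::mat& emb,
                           const arma::mat& Wf, const arma::mat& Wb) {
  const int n = char_ids.size();
  const uword H = Wf.n_rows / 4;
  mat feats(2 * H, n, fill::zeros);
  Rcpp::List caches(n);
  for (int k = 0; k < n; ++k) {
    Rcpp::IntegerVector ids = char_ids[k];
    const uword Lc = ids.size();
    mat X(emb.n_cols, Lc);
    for (uword t = 0; t < Lc; ++t) X.col(t) = emb.row(ids[t] - 1).t();
    mat Xr = fliplr(X);
    Rcpp::List fw = cpp_lstm_forward(X, Wf);
    Rcpp::List bw = cpp_lstm_forward(Xr, Wb);
    mat hf = fw["h"], hb = bw["h"];
    feats.col(k) = join_cols(hf.col(Lc - 1), hb.col(Lc - 1));
    caches[k] = Rcpp::List::create(Rcpp::Named("X") = X,
                                   Rcpp::Named("fw") = fw,
                                   Rcpp::Named("bw") = bw);
  }
  return Rcpp::List::create(Rcpp::Named("feats") = feats,
                            Rcpp::Named("caches") = caches);
}

// Backward for the character encoder.  dfeats is 2H x n_tokens.  Returns
// gradient on the character embedding table and on both weight matrices.
// [[Rcpp::export]]
Rcpp::List cpp_char_encode_backward(const Rcpp::List& char_ids,
                                    const arma::mat& emb,
                                    const arma::mat& Wf, const arma::mat& Wb,
                                    const Rcpp::List& caches,
                                    const arma::mat& dfeats) {
  const int n = char_ids.size();
  const uword H = Wf.n_rows / 4;
  mat dEmb(size(emb), fill::zeros);
  mat dWf(size(Wf), fill::zeros), dWb(size(Wb), fill::zeros);
  for (int k = 0; k < n; ++k) {
    Rcpp::IntegerVector ids = char_ids[k];
    const uword Lc = ids.size();
    Rcpp::List cache = caches[k];
    mat X = cache["X"];
    Rcpp::List fw = cache["fw"], bw = cache["bw"];
    mat dh_f(H, Lc, fill::zeros), dh_b(H, Lc, fill::zeros);
    dh_f.col(Lc - 1) = dfeats.col(k).subvec(0, H - 1);
    dh_b.col(Lc - 1) = dfeats.col(k).subvec(H, 2 * H - 1);
    Rcpp::List gf_ = cpp_lstm_backward(X, Wf, fw["h"], fw["c"], fw["gates"], dh_f);
    mat Xr = fliplr(X);
    Rcpp::List gb_ = cpp_lstm_backward(Xr, Wb, bw["h"], bw["c"], bw["gates"], dh_b);
    dWf += Rcpp::as<mat>(gf_["dW"]);
    dWb += Rcpp::as<mat>(gb_["dW"]);
    mat dX = Rcpp::as<mat>(gf_["dX"]) + fliplr(Rcpp::as<mat>(gb_["dX"]));
    for (uword t = 0; t < Lc; ++t) dEmb.row(ids[t] - 1) += dX.col(t).t();
  }
  return Rcpp::List::create(Rcpp::Named("dEmb") = dEmb,
                            Rcpp::Named("dWf") = dWf,
                            Rcpp::Named("dWb") = dWb);
}
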