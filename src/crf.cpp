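// Linear-chain CRF: log-partition via the forward recursion, posterior
// gradients via forward-backward, and Viterbi decoding.
//
// Conventions: emissions is K x L (tags in rows, positions in columns);
// transitions is (K+2) x (K+2) with row/col K (0-based) the virtual START
// state and K+1 the virtual STOP state; transitions[i, j] scores moving
// from i to j.  Entries may be -Inf (hard-masked transitions).

#include <RcppArmadillo.h>
#include <limits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double log_sum_exp(const vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;  // all -Inf (or contains +Inf/NaN upstream)
  return m + std::log(accu(exp(x - m)));
}

// Score of one tag path: sum of emissions plus transitions including the
// START -> tags[0] and tags[L-1] -> STOP terms.  tags are 1-based.
// [[Rcpp::export]]
double cpp_crf_score(const arma::mat& emissions, const arma::mat& transitions,
                     const Rcpp::IntegerVector& tags) {
  const uword K = emissions.n_rows, L = emissions.n_cols;
  if ((uword)tags.size() != L) Rcpp::stop("tag path length != sentence length");
  const uword START = K, STOP = K + 1;
  double s = 0.0;
  uword prev = START;
  for (uword t = 0; t < L; ++t) {
    uword j = (uword)(tags[t] - 1);
    if (j >= K) Rcpp::stop("tag index out of range at position %d", (int)t + 1);
    s += transitions(prev, j) + emissions(j, t);
    prev = j;
  }
  s += transitions(prev, STOP);
  return s;
}

// Log-partition and, optionally, the gradients of logZ with respect to the
// emissions (posterior marginals) and the transitions (expected transition
// counts), computed by forward-backward in log space.
// [[Rcpp::export]]
Rcpp::List cpp_crf_forward(const arma::mat& emissions,
                           const arma::mat& transitions,
                           const bool grad = true) {
  const uword K = emissions.n_rows, L = emissions.n_cols;
  const uword START = K, STOP = K + 1;
  if (L == 0) Rcpp::stop("empty sentence");

  mat alpha(K, L);
  alpha.col(0) = transitions.submat(START, 0, START, K - 1).t() + emissions.col(0);
  for (uword t = 1; t < L; ++t)
    for (uword j = 0; j < K; ++j)
      alpha(j, t) = emissions(j, t) +
        log_sum_exp(alpha.col(t - 1) + transitions.submat(0, j, K - 1, j));
  double logZ = log_sum_exp(alpha.col(L - 1) +
                            transitions.submat(0, STOP, K - 1, STOP));
  if (!std::isfinite(logZ))
    Rcpp::stop("log-partition is not finite: transition mask admits no path");
  if (!grad)
    return Rcpp::List::create(Rcpp::Named("logZ") = logZ);

  mat beta(K, L);
  beta.col(L - 1) = transitions.submat(0, STOP, K - 1, STOP);
  for (uword t = L - 1; t-- > 0;)
    for (uword j = 0; j < K; ++j)
      beta(j, t) = log_sum_exp(transitions.submat(j, 0, j, K - 1).t() +
                               emissions.col(t + 1) + beta.col(t + 1));

  mat dE = exp(alpha + beta - logZ);  // posterior marginals, K x L
  mat dT(K + 2, K + 2, fill::zeros);
  dT.submat(START, 0, START, K - 1) = dE.col(0).t();
  dT.submat(0, STOP, K - 1, STOP) = dE.col(L - 1);
  for (uword t = 1; t < L; ++t) {
    // joint posterior of (i at t-1, j at t)
    for (uword j = 0; j < K; ++j) {
      vec lg = alpha.col(t - 1) + transitions.submat(0, j, K - 1, j) +
               emissions(j, t) + beta(j, t) - logZ;
      for (uword i = 0; i < K; ++i)
        if (std::isfinite(lg(i))) dT(i, j) += std::exp(lg(i));
    }
  }
  return Rcpp::List::create(Rcpp::Named("logZ") = logZ,
                            Rcpp::Named("dE") = dE,
                            Rcpp::Named("dT") = dT);
}

// Viterbi decoding.  Ties are broken toward the lowest tag index (strict >
// comparison while scanning in index order), making the argmax deterministic.
// Returns the 1-based best path and its score.
// [[Rcpp::export]]
Rcpp::List cpp_crf_viterbi(const arma::mat& emissions,
                           const arma::mat& transitions) {
  const uword K = emissions.n_rows, L = emissions.n_cols;
  const uword START = K, STOP = K + 1;
  if (L == 0) Rcpp::stop("empty sentence");

  mat delta(K, L);
  umat back(K, L, fill::zeros);
  delta.col(0) = transitions.submat(START, 0, START, K - 1).t() + emissions.col(0);
  for (uword t = 1; t < L; ++t) {
    for (uword j = 0; j < K; ++j) {
      double best = NEG_INF;
      uword arg = 0;
      for (uword i = 0; i < K; ++i) {
        double v = delta(i, t - 1) + transitions(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(j, t) = best + emissions(j, t);
      back(j, t) = arg;
    }
  }
  double best = NEG_INF;
  uword arg = 0;
  for (uword j = 0; j < K; ++j) {
    double v = delta(j, L - 1) + transitions(j, STOP);
    if (v > best) { best = v; arg = j; }
  }
  if (!std::isfinite(best))
    Rcpp::stop("no admissible path under the transition mask");
  Rcpp::IntegerVector path(L);
  uword cur = arg;
  for (uword t = L; t-- > 0;) {
    path[t] = (int)cur + 1;
    if (t > 0) cur = back(cur, t);
  }
  return Rcpp::List::create(Rcpp::Named("path") = path,
                            Rcpp::Named("score") = best);
}
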