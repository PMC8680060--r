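// Levenshtein distance over Unicode code points.  The R wrappers convert
// strings with utf8ToInt() so multi-byte characters count as one symbol.

#include <Rcpp.h>
#include <vector>
#include <algorithm>

// [[Rcpp::export]]
int cpp_levenshtein(const Rcpp::IntegerVector& a, const Rcpp::IntegerVector& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, sub});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Distance from one query against many candidate terms (each already
// converted to code points).  Used by the dictionary search stages.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_levenshtein_many(const Rcpp::IntegerVector& query,
                                         const Rcpp::List& terms) {
  const int n = terms.size();
  Rcpp::IntegerVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = cpp_levenshtein(query, terms[k]);
  return out;
}
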