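#include <Rcpp.h>
using namespace Rcpp;

// Best local-alignment score, linear (per-base) gap penalty.
// Rolling two-row DP; scores never drop below 0 (local alignment).
static double sw_one(const std::string& a, const std::string& b,
                     double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double v = prev[j - 1] + s;
      if (prev[j] + gap > v) v = prev[j] + gap;
      if (cur[j - 1] + gap > v) v = cur[j - 1] + gap;
      if (v < 0.0) v = 0.0;
      cur[j] = v;
      if (v > best) best = v;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(std::string a, std::string b,
                    double match, double mismatch, double gap) {
  return sw_one(a, b, match, mismatch, gap);
}

// All-pairs raw local-alignment scores, including the diagonal self-scores.
// [[Rcpp::export(name = ".sw_pairwise_cpp")]]
NumericMatrix sw_pairwise_cpp(CharacterVector seqs,
                              double match, double mismatch, double gap) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = sw_one(s[i], s[i], match, mismatch, gap);
    for (int j = i + 1; j < n; ++j) {
      double v = sw_one(s[i], s[j], match, mismatch, gap);
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
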