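#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Deterministic uniform in [0,1) from mt19937_64; avoids the
// implementation-defined behaviour of std::uniform_real_distribution.
static inline double runif01(std::mt19937_64& gen) {
  return (gen() >> 11) * (1.0 / 9007199254740992.0);  // 53-bit mantissa
}

static inline int sample_cumulative(const std::vector<double>& cum,
                                    std::mt19937_64& gen) {
  double u = runif01(gen) * cum.back();
  return std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
}

static inline bool is_neighbor(const IntegerVector& indptr,
                               const IntegerVector& nbr, int u, int x) {
  const int lo = indptr[u], hi = indptr[u + 1];
  return std::binary_search(nbr.begin() + lo, nbr.begin() + hi, x);
}

// Second-order (p,q)-biased random walks over a CSR graph.
// indptr: length n+1; nbr: 0-based sorted neighbor ids; wt: edge weights.
// Returns an integer matrix [num_walks*n x walk_length], -1 padded
// (isolated nodes emit length-1 walks).  First step is first-order
// weight-proportional; later steps multiply the node2vec alpha bias.
// [[Rcpp::export(name = ".node2vec_walks_cpp")]]
IntegerMatrix node2vec_walks_cpp(IntegerVector indptr, IntegerVector nbr,
                                 NumericVector wt, int n, double p, double q,
                                 int walk_length, int num_walks, int seed) {
  std::mt19937_64 gen(static_cast<uint64_t>(seed));
  IntegerMatrix walks(num_walks * n, walk_length);
  std::fill(walks.begin(), walks.end(), -1);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> cum;
  int row = 0;
  for (int w = 0; w < num_walks; ++w) {
    // fresh node order each pass (Fisher-Yates)
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(runif01(gen) * (i + 1));
      std::swap(order[i], order[j]);
    }
    for (int s = 0; s < n; ++s, ++row) {
      int cur = order[s], prev = -1;
      walks(row, 0) = cur;
      for (int step = 1; step < walk_length; ++step) {
        const int lo = indptr[cur], hi = indptr[cur + 1];
        if (hi == lo) break;  // dead end: walk terminates
        cum.assign(hi - lo, 0.0);
        double acc = 0.0;
        for (int k = lo; k < hi; ++k) {
          double a = 1.0;
          if (prev >= 0) {
            int x = nbr[k];
            if (x == prev) a = 1.0 / p;
            else if (!is_neighbor(indptr, nbr, prev, x)) a = 1.0 / q;
          }
          acc += wt[k] * a;
          cum[k - lo] = acc;
        }
        int pick = lo + sample_cumulative(cum, gen);
        prev = cur;
        cur = nbr[pick];
        walks(row, step) = cur;
      }
    }
  }
  return walks;
}

// Skip-gram with negative sampling over a walk corpus (-1 padded rows).
// Single-threaded, fully deterministic given the seed.  Negative-sampling
// distribution is the corpus unigram frequency raised to 3/4.  Learning
// rate decays linearly from alpha0 to alpha0/1e4.  Returns the input
// ("center") embedding matrix [n_nodes x d].
// [[Rcpp::export(name = ".skipgram_cpp")]]
NumericMatrix skipgram_cpp(IntegerMatrix walks, int n_nodes, int d,
                           int window, int epochs, int negative,
                           double alpha0, int seed) {
  std::mt19937_64 gen(static_cast<uint64_t>(seed) * 2654435761u + 1u);
  const int n_walks = walks.nrow(), wl = walks.ncol();

  std::vector<double> freq(n_nodes, 0.0);
  long long n_tokens = 0;
  for (int r = 0; r < n_walks; ++r)
    for (int c = 0; c < wl; ++c) {
      int v = walks(r, c);
      if (v < 0) break;
      freq[v] += 1.0;
      ++n_tokens;
    }
  std::vector<double> neg_cum(n_nodes);
  double acc = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    acc += std::pow(freq[v], 0.75);
    neg_cum[v] = acc;
  }
  if (acc <= 0.0) stop("empty walk corpus");

  // row-contiguous layout [node*d + k] keeps the inner loops cache-friendly
  std::vector<double> win(static_cast<size_t>(n_nodes) * d);
  std::vector<double> wout(static_cast<size_t>(n_nodes) * d, 0.0);
  for (size_t t = 0; t < win.size(); ++t)
    win[t] = (runif01(gen) - 0.5) / d;

  std::vector<double> grad(d);
  const double total = static_cast<double>(n_tokens) * epochs;
  double seen = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int r = 0; r < n_walks; ++r) {
      for (int c = 0; c < wl; ++c) {
        int center = walks(r, c);
        if (center < 0) break;
        seen += 1.0;
        double alpha = alpha0 * std::max(1.0 - seen / total, 1e-4);
        int b = 1 + static_cast<int>(runif01(gen) * window);  // reduced window
        int lo = std::max(0, c - b), hi = std::min(wl - 1, c + b);
        for (int cc = lo; cc <= hi; ++cc) {
          int ctx = walks(r, cc);
          if (ctx < 0) break;
          if (cc == c) continue;
          std::fill(grad.begin(), grad.end(), 0.0);
          double* ci = &win[static_cast<size_t>(center) * d];
          for (int s = 0; s < negative + 1; ++s) {
            int target;
            double label;
            if (s == 0) { target = ctx; label = 1.0; }
            else {
              target = sample_cumulative(neg_cum, gen);
              if (target == ctx) continue;
              label = 0.0;
            }
            double* o = &wout[static_cast<size_t>(target) * d];
            double dot = 0.0;
            for (int k = 0; k < d; ++k) dot += ci[k] * o[k];
            double g = (label - 1.0 / (1.0 + std::exp(-dot))) * alpha;
            for (int k = 0; k < d; ++k) {
              grad[k] += g * o[k];
              o[k] += g * ci[k];
            }
          }
          for (int k = 0; k < d; ++k) ci[k] += grad[k];
        }
      }
    }
  }
  NumericMatrix out(n_nodes, d);
  for (int v = 0; v < n_nodes; ++v)
    for (int k = 0; k < d; ++k)
      out(v, k) = win[static_cast<size_t>(v) * d + k];
  return out;
}
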