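// Single-threaded skip-gram negative-sampling trainer.
//
// Classic word2vec-style SGNS: dynamic (uniformly shrunk) context window,
// frequency subsampling of common tokens, unigram^0.75 negative-sampling
// distribution, linear learning-rate decay over epochs * corpus size.
// Single-threaded on purpose: with a fixed seed the trained vectors are
// bit-reproducible run to run on the same platform.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xorshift64* PRNG: fast, seedable, platform-independent
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t x = state;
    x ^= x >> 12;
    x ^= x << 25;
    x ^= x >> 27;
    state = x;
    return x * 0x2545F4914F6CDD1DULL;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".sgns_train")]]
NumericMatrix sgns_train(List docs, IntegerVector counts, int dim, int window,
                         int negative, double alpha, double min_alpha,
                         double sample, int epochs, int seed) {
  const int vocab = counts.size();
  const double total = std::accumulate(counts.begin(), counts.end(), 0.0);

  // subsampling keep-probabilities (word2vec formula); sample <= 0 disables
  std::vector<double> keep(vocab, 1.0);
  if (sample > 0) {
    for (int i = 0; i < vocab; ++i) {
      double f = counts[i] / total;
      double p = (std::sqrt(f / sample) + 1.0) * sample / f;
      keep[i] = p < 1.0 ? p : 1.0;
    }
  }

  // cumulative unigram^0.75 table for negative sampling via binary search
  std::vector<double> cum(vocab);
  double z = 0.0;
  for (int i = 0; i < vocab; ++i) {
    z += std::pow(static_cast<double>(counts[i]), 0.75);
    cum[i] = z;
  }

  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);

  std::vector<double> syn0(static_cast<size_t>(vocab) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  const double train_words = total * epochs;
  double processed = 0.0;
  std::vector<double> grad(dim);
  std::vector<int> sent;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < docs.size(); ++d) {
      IntegerVector doc = docs[d];
      sent.clear();
      for (int k = 0; k < doc.size(); ++k) {
        processed += 1.0;
        int w = doc[k];
        if (keep[w] >= 1.0 || rng.unif() < keep[w]) sent.push_back(w);
      }
      double lr = alpha - (alpha - min_alpha) * (processed / train_words);
      if (lr < min_alpha) lr = min_alpha;

      const int n = static_cast<int>(sent.size());
      for (int pos = 0; pos < n; ++pos) {
        const int center = sent[pos];
        const int shrink = rng.below(window); // dynamic window in [1, window]
        const int lo = std::max(0, pos - window + shrink);
        const int hi = std::min(n - 1, pos + window - shrink);
        for (int c = lo; c <= hi; ++c) {
          if (c == pos) continue;
          const int ctx = sent[c];
          double* v_in = &syn0[static_cast<size_t>(center) * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = ctx;
              label = 1.0;
            } else {
              double r = rng.unif() * z;
              target = static_cast<int>(
                  std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
              if (target >= vocab) target = vocab - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double dot = 0.0;
            for (int j = 0; j < dim; ++j) dot += v_in[j] * v_out[j];
            const double g = (label - sigmoid(dot)) * lr;
            for (int j = 0; j < dim; ++j) {
              grad[j] += g * v_out[j];
              v_out[j] += g * v_in[j];
            }
          }
          for (int j = 0; j < dim; ++j) v_in[j] += grad[j];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int j = 0; j < dim; ++j)
      out(i, j) = syn0[static_cast<size_t>(i) * dim + j];
  return out;
}
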