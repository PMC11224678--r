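#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64). Training must be
// bit-reproducible under a seed, independent of R's RNG state.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in {0, ..., n-1}
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

static inline uint64_t mix3(uint64_t a, uint64_t b, uint64_t c) {
  uint64_t h = a * 0x9E3779B97F4A7C15ULL;
  h ^= b + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
  h *= 0xBF58476D1CE4E5B9ULL;
  h ^= c + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
  return h;
}

static inline double sigmoid(double x) {
  if (x >= 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// One SGD step on the SGNS loss
//   L = -log s(u_pos . v) - sum_i log s(-u_neg_i . v)
// w.r.t. v_target, u_pos and each u_neg. Gradients use the pre-update
// values of all rows (accumulate-then-apply, as in word2vec). Matrices are
// modified IN PLACE; indices are 0-based.
// [[Rcpp::export]]
void cpp_sgns_step(NumericMatrix W, NumericMatrix C, int target, int context,
                   IntegerVector negatives, double lr) {
  const int d = W.ncol();
  std::vector<double> v(d), gv(d, 0.0);
  for (int j = 0; j < d; ++j) v[j] = W(target, j);

  double dot = 0.0;
  for (int j = 0; j < d; ++j) dot += C(context, j) * v[j];
  double g = sigmoid(dot) - 1.0;  // dL/d(dot) for the positive pair
  for (int j = 0; j < d; ++j) {
    gv[j] += g * C(context, j);
    C(context, j) -= lr * g * v[j];
  }
  for (int k = 0; k < negatives.size(); ++k) {
    int neg = negatives[k];
    dot = 0.0;
    for (int j = 0; j < d; ++j) dot += C(neg, j) * v[j];
    g = sigmoid(dot);  // dL/d(dot) for a negative pair
    for (int j = 0; j < d; ++j) {
      gv[j] += g * C(neg, j);
      C(neg, j) -= lr * g * v[j];
    }
  }
  for (int j = 0; j < d; ++j) W(target, j) -= lr * gv[j];
}

static int sample_cdf(const std::vector<double>& cdf, double u) {
  // first index with cdf[i] > u
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// Full skip-gram-with-negative-sampling training loop.
//
// docs: list of integer vectors of 0-based vocabulary indices (one per cell,
//       unique words within a document). Each document is re-shuffled with a
//       fresh Fisher-Yates permutation every epoch, seeded from
//       (seed, epoch, document index), simulating co-accessibility context.
// For each position t an effective window b ~ Uniform{1..window} is drawn
// and (target, context) pairs are emitted for all contexts within distance
// b. Learning rate is alpha0 * decay^epoch, constant within an epoch.
// Negatives are drawn from noise_cdf (cumulative probabilities over the
// vocabulary) and resampled when equal to the positive context.
// [[Rcpp::export]]
List cpp_train_sgns(List docs, int vocab_size, int dim, int window, int epochs,
                    double alpha0, double decay, int k_neg,
                    NumericVector noise_cdf, double seed) {
  const int V = vocab_size, d = dim;
  const uint64_t useed = (uint64_t)seed;
  std::vector<double> W((size_t)V * d), Cm((size_t)V * d, 0.0);

  SplitMix init_rng(mix3(useed, 0x1234567ULL, 0xFEDCBAULL));
  for (size_t i = 0; i < W.size(); ++i) W[i] = (init_rng.unif() - 0.5) / d;

  std::vector<double> cdf(noise_cdf.begin(), noise_cdf.end());
  const int ndoc = docs.size();
  std::vector<std::vector<int>> dvec(ndoc);
  for (int i = 0; i < ndoc; ++i) {
    IntegerVector di = docs[i];
    dvec[i].assign(di.begin(), di.end());
  }

  std::vector<double> v(d), gv(d);
  std::vector<int> doc;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    const double lr = alpha0 * std::pow(decay, epoch);
    for (int di = 0; di < ndoc; ++di) {
      const std::vector<int>& src = dvec[di];
      const int n = (int)src.size();
      if (n == 0) continue;
      SplitMix rng(mix3(useed, (uint64_t)epoch + 1, (uint64_t)di + 1));
      doc = src;
      for (int i = n - 1; i > 0; --i) std::swap(doc[i], doc[rng.below(i + 1)]);
      if (n == 1) continue;
      for (int t = 0; t < n; ++t) {
        const int b = 1 + rng.below(window);
        const int target = doc[t];
        const int lo = t - b < 0 ? 0 : t - b;
        const int hi = t + b >= n ? n - 1 : t + b;
        for (int c = lo; c <= hi; ++c) {
          if (c == t) continue;
          const int context = doc[c];
          double* vt = &W[(size_t)target * d];
          for (int j = 0; j < d; ++j) { v[j] = vt[j]; gv[j] = 0.0; }
          double* up = &Cm[(size_t)context * d];
          double dot = 0.0;
          for (int j = 0; j < d; ++j) dot += up[j] * v[j];
          double g = sigmoid(dot) - 1.0;
          for (int j = 0; j < d; ++j) {
            gv[j] += g * up[j];
            up[j] -= lr * g * v[j];
          }
          for (int k = 0; k < k_neg; ++k) {
            int neg = sample_cdf(cdf, rng.unif());
            int tries = 0;
            while (neg == context && V > 1 && ++tries < 100)
              neg = sample_cdf(cdf, rng.unif());
            double* un = &Cm[(size_t)neg * d];
            dot = 0.0;
            for (int j = 0; j < d; ++j) dot += un[j] * v[j];
            g = sigmoid(dot);
            for (int j = 0; j < d; ++j) {
              gv[j] += g * un[j];
              un[j] -= lr * g * v[j];
            }
          }
          for (int j = 0; j < d; ++j) vt[j] -= lr * gv[j];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix Wout(V, d), Cout(V, d);
  for (int w = 0; w < V; ++w)
    for (int j = 0; j < d; ++j) {
      Wout(w, j) = W[(size_t)w * d + j];
      Cout(w, j) = Cm[(size_t)w * d + j];
    }
  return List::create(_["input"] = Wout, _["context"] = Cout);
}
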