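#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

// Deterministic uniforms from a raw mt19937 stream (avoids
// implementation-defined std::uniform_* distributions).
static inline double unif01(std::mt19937 &rng) {
  return (static_cast<double>(rng()) + 0.5) / 4294967296.0;
}

static inline double sigmoid(double x) {
  if (x > 8.0) return 1.0 / (1.0 + std::exp(-8.0));
  if (x < -8.0) return 1.0 / (1.0 + std::exp(8.0));
  return 1.0 / (1.0 + std::exp(-x));
}

// Skip-gram with negative sampling over integer-coded walks (0-based).
// Single-threaded; all randomness comes from `seed`, so output is
// reproducible bit-for-bit. iterations = 0 returns the initialization.
// [[Rcpp::export]]
NumericMatrix sgns_train(List walks, int n_nodes, int dim, int window,
                         int iterations, int negative, double alpha,
                         double min_alpha, int seed) {
  std::mt19937 rng(static_cast<uint32_t>(seed));

  // init: syn0 ~ U(-0.5/dim, 0.5/dim), syn1 (output vectors) at zero
  std::vector<double> syn0(static_cast<size_t>(n_nodes) * dim);
  std::vector<double> syn1(static_cast<size_t>(n_nodes) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (unif01(rng) - 0.5) / dim;

  // unigram^(3/4) noise table
  const int n_walks = walks.size();
  std::vector<double> counts(n_nodes, 0.0);
  long long total_positions = 0;
  std::vector<IntegerVector> wv;
  wv.reserve(n_walks);
  for (int k = 0; k < n_walks; ++k) {
    IntegerVector w = walks[k];
    wv.push_back(w);
    total_positions += w.size();
    for (int t = 0; t < w.size(); ++t) {
      int v = w[t];
      if (v < 0 || v >= n_nodes) stop("walk node index out of range");
      counts[v] += 1.0;
    }
  }
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    for (int v = 0; v < n_nodes; ++v) z += std::pow(counts[v], 0.75);
    int v = 0;
    double cum = std::pow(counts[0], 0.75) / z;
    for (int a = 0; a < table_size; ++a) {
      table[a] = v;
      if ((a + 1.0) / table_size > cum && v < n_nodes - 1) {
        ++v;
        cum += std::pow(counts[v], 0.75) / z;
      }
    }
  }

  std::vector<double> neu1e(dim);
  const long long total_work = total_positions * (long long)iterations;
  long long processed = 0;

  for (int it = 0; it < iterations; ++it) {
    for (int k = 0; k < n_walks; ++k) {
      const IntegerVector &w = wv[k];
      const int len = w.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)processed / (double)(total_work + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        // reduced window, as in classical word2vec
        int b = (int)(rng() % (uint32_t)window);
        int lo = pos - (window - b); if (lo < 0) lo = 0;
        int hi = pos + (window - b); if (hi > len - 1) hi = len - 1;
        const int center = w[pos];
        double *v0 = &syn0[(size_t)center * dim];
        for (int p = lo; p <= hi; ++p) {
          if (p == pos) continue;
          const int ctx = w[p];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d <= negative; ++d) {
            int target; double label;
            if (d == 0) {
              target = ctx; label = 1.0;
            } else {
              target = table[rng() % (uint32_t)table_size];
              if (target == ctx) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int j = 0; j < dim; ++j) f += v0[j] * v1[j];
            double g = (label - sigmoid(f)) * lr;
            for (int j = 0; j < dim; ++j) neu1e[j] += g * v1[j];
            for (int j = 0; j < dim; ++j) v1[j] += g * v0[j];
          }
          for (int j = 0; j < dim; ++j) v0[j] += neu1e[j];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int v = 0; v < n_nodes; ++v)
    for (int j = 0; j < dim; ++j)
      out(v, j) = syn0[(size_t)v * dim + j];
  return out;
}
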