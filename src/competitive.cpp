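#include <Rcpp.h>
using namespace Rcpp;

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG
static inline uint64_t xs_next(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}

// uniform integer in [0, n)
static inline int xs_below(uint64_t &s, int n) {
  return (int)(xs_next(s) % (uint64_t)n);
}

// Kohonen competitive (winner-take-all) training.
// X: n x d feature matrix (already standardized), w0: L x d initial
// weights. Per epoch the presentation order is a Fisher-Yates shuffle
// driven by the xorshift state seeded from `seed`; the learning rate
// decays linearly from lr_start to lr_end across epochs. Only the winner
// (minimum Euclidean distance, ties to the lower index) is updated.
// [[Rcpp::export]]
NumericMatrix competitive_train_cpp(const NumericMatrix &X,
                                    const NumericMatrix &w0,
                                    int epochs, double lr_start,
                                    double lr_end, double seed) {
  const int n = X.nrow(), d = X.ncol(), L = w0.nrow();
  NumericMatrix W = clone(w0);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  uint64_t state = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  if (state == 0) state = 0x9E3779B97F4A7C15ULL;

  for (int e = 0; e < epochs; ++e) {
    double eta = (epochs == 1) ? lr_start
      : lr_start + (lr_end - lr_start) * (double)e / (double)(epochs - 1);
    // Fisher-Yates
    for (int i = n - 1; i > 0; --i) {
      int j = xs_below(state, i + 1);
      std::swap(order[i], order[j]);
    }
    for (int ii = 0; ii < n; ++ii) {
      int i = order[ii];
      int win = 0;
      double best = R_PosInf;
      for (int l = 0; l < L; ++l) {
        double dist = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = X(i, k) - W(l, k);
          dist += diff * diff;
        }
        if (dist < best) { best = dist; win = l; }
      }
      for (int k = 0; k < d; ++k) {
        W(win, k) += eta * (X(i, k) - W(win, k));
      }
    }
  }
  return W;
}
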