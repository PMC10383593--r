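#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// one row update; returns nothing, accumulates the center-row error in neule.
// Mirrors pairUpdate() in R/train.R: keep the two in lockstep.
static inline void update_pair(NumericMatrix& f, NumericMatrix& fout,
                               std::vector<double>& neule,
                               int u, int n, double label, double lr,
                               bool graphMode, double m, bool wInside,
                               int d) {
  double s = 0.0;
  for (int j = 0; j < d; ++j) s += f(u, j) * fout(n, j);
  double g, scale;
  if (!graphMode) {
    g = (label - sigmoid(s)) * lr;
    scale = 1.0;
  } else {
    double A = wInside ? sigmoid(s * m) : sigmoid(s) * m;
    if (A > 1.0) A = 1.0;
    if (A < -1.0) A = -1.0;
    g = (label - A) * lr;
    scale = m;
  }
  // accumulator uses the context row BEFORE it is updated
  for (int j = 0; j < d; ++j) neule[j] += fout(n, j) * g * scale;
  for (int j = 0; j < d; ++j) fout(n, j) += f(u, j) * g * scale;
}

// Negative-sampling SGD over a fixed pair stream. pairs: two-column
// 1-based (center, context) row indices. f and fout are modified in
// place. noiseCdf: cumulative noise probabilities over node rows.
// mult: optional dense multiplier matrix W^L (rows = center). Uses R's
// RNG (unif_rand) so a set.seed() in the caller makes runs
// bit-reproducible.
// [[Rcpp::export]]
List sgd_train_cpp(IntegerMatrix pairs, NumericMatrix f, NumericMatrix fout,
                   NumericVector noiseCdf, int k, double alpha0,
                   double alphaMin, Nullable<NumericMatrix> mult,
                   bool wInside) {
  const int d = f.ncol();
  const int nNodes = f.nrow();
  const R_xlen_t nPairs = pairs.nrow();
  const bool graphMode = mult.isNotNull();
  NumericMatrix M;
  if (graphMode) M = mult.get();

  IntegerVector posV(nNodes), posC(nNodes), negCnt(nNodes);
  std::vector<double> neule(d);
  RNGScope rngScope;

  for (R_xlen_t t = 0; t < nPairs; ++t) {
    double lr = alpha0 * (1.0 - (double)t / (double)nPairs);
    if (lr < alphaMin) lr = alphaMin;
    const int u = pairs(t, 0) - 1;
    const int n = pairs(t, 1) - 1;
    std::fill(neule.begin(), neule.end(), 0.0);

    // positive pair (walk-sampled: reachable, L = 1)
    update_pair(f, fout, neule, u, n, 1.0, lr, graphMode,
                graphMode ? M(u, n) : 1.0, wInside, d);
    posV[u] += 1;
    posC[n] += 1;

    for (int i = 0; i < k; ++i) {
      int ni = u;
      while (ni == u) {
        double r = unif_rand();
        // binary search the cdf
        int lo = 0, hi = nNodes - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (noiseCdf[mid] < r) lo = mid + 1; else hi = mid;
        }
        ni = lo;
      }
      update_pair(f, fout, neule, u, ni, 0.0, lr, graphMode,
                  graphMode ? M(u, ni) : 1.0, wInside, d);
      negCnt[ni] += 1;
    }

    for (int j = 0; j < d; ++j) f(u, j) += neule[j];
  }

  return List::create(_["posV"] = posV, _["posC"] = posC,
                      _["neg"] = negCnt);
}
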