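#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exact leave-one-out prediction for the distance-based classifiers (kNN and
// the Parzen-kernel PNN) under per-fold z-score standardization.
//
// Because both held-out query and training points are centred with the same
// fold mean, the mean cancels in every pairwise difference; only the fold
// variances enter. With per-feature squared-difference matrices D_f
// precomputed once, the round-i squared distance is
//     d2(i, j) = sum_f D_f(i, j) / var_{-i, f}
// with var_{-i,f} the unbiased variance of feature f over the fold that
// excludes i (denominator n - 2). The fold RMS pairwise training distance
// (the PNN spread scale) has the same closed form via the per-feature row
// sums and grand totals of D_f. These identities make this path bit-exact
// with respect to the naive fit/predict loop; the equivalence is asserted in
// the test suite.

struct LooWorkspace {
  int n, k, nclass;
  std::vector<double> X;     // n x k, column-major
  std::vector<double> D;     // n x n x k squared differences
  std::vector<double> rowsum; // n x k: sum_j D_f(i, j)
  std::vector<double> total;  // k: sum_{i<j} D_f(i, j)
  std::vector<double> S, Q;   // per-feature sum and sum of squares
  std::vector<int> y;         // 0-based labels
  std::vector<int> ccount;    // class counts
};

static LooWorkspace build_workspace(const NumericMatrix& X, const IntegerVector& y) {
  LooWorkspace w;
  w.n = X.nrow();
  w.k = X.ncol();
  w.X.assign(X.begin(), X.end());
  w.y.assign(y.begin(), y.end());
  w.nclass = 0;
  for (int i = 0; i < w.n; ++i) w.nclass = std::max(w.nclass, w.y[i] + 1);
  w.ccount.assign(w.nclass, 0);
  for (int i = 0; i < w.n; ++i) w.ccount[w.y[i]]++;
  w.D.assign((size_t)w.n * w.n * w.k, 0.0);
  w.rowsum.assign((size_t)w.n * w.k, 0.0);
  w.total.assign(w.k, 0.0);
  w.S.assign(w.k, 0.0);
  w.Q.assign(w.k, 0.0);
  for (int f = 0; f < w.k; ++f) {
    const double* x = &w.X[(size_t)f * w.n];
    double* Df = &w.D[(size_t)f * w.n * w.n];
    for (int i = 0; i < w.n; ++i) {
      w.S[f] += x[i];
      w.Q[f] += x[i] * x[i];
    }
    for (int i = 0; i < w.n; ++i) {
      for (int j = i + 1; j < w.n; ++j) {
        double d = x[i] - x[j];
        d *= d;
        Df[i + (size_t)j * w.n] = d;
        Df[j + (size_t)i * w.n] = d;
        w.rowsum[i + (size_t)f * w.n] += d;
        w.rowsum[j + (size_t)f * w.n] += d;
        w.total[f] += d;
      }
    }
  }
  return w;
}

// Predictions (0-based classes) for one feature subset.
// method: 0 = kNN, 1 = PNN. sigma_abs > 0 overrides sigma_mult.
static void loo_predict_subset(const LooWorkspace& w, const std::vector<int>& fs,
                               int method, int knn_k, double sigma_abs,
                               double sigma_mult, std::vector<int>& pred) {
  const int n = w.n;
  const double npairs = (double)(n - 1) * (n - 2) / 2.0;
  std::vector<double> d2(n), wgt(fs.size());
  std::vector<double> score(w.nclass);
  std::vector<int> votes(w.nclass), sel(std::max(knn_k, 1));
  pred.assign(n, 0);

  for (int i = 0; i < n; ++i) {
    double rms2 = 0.0;
    for (size_t a = 0; a < fs.size(); ++a) {
      int f = fs[a];
      double xi = w.X[i + (size_t)f * n];
      double m = (w.S[f] - xi) / (n - 1);
      double ss = w.Q[f] - xi * xi - (double)(n - 1) * m * m;
      double v = ss / (n - 2);
      wgt[a] = (v > 1e-12) ? 1.0 / v : 1.0;  // constant feature: unit scale
      rms2 += wgt[a] * (w.total[f] - w.rowsum[i + (size_t)f * n]);
    }
    rms2 /= npairs;
    for (int j = 0; j < n; ++j) d2[j] = 0.0;
    for (size_t a = 0; a < fs.size(); ++a) {
      const double* Df = &w.D[(size_t)fs[a] * n * n];
      const double wa = wgt[a];
      for (int j = 0; j < n; ++j) d2[j] += wa * Df[i + (size_t)j * n];
    }
    d2[i] = R_PosInf;

    if (method == 0) {  // kNN: k nearest by stable selection, majority vote
      std::vector<char> used(n, 0);
      for (int a = 0; a < knn_k; ++a) {
        int best = -1;
        for (int j = 0; j < n; ++j)
          if (!used[j] && j != i && (best < 0 || d2[j] < d2[best])) best = j;
        used[best] = 1;
        sel[a] = best;
      }
      std::fill(votes.begin(), votes.end(), 0);
      for (int a = 0; a < knn_k; ++a) votes[w.y[sel[a]]]++;
      int maxv = 0;
      for (int c = 0; c < w.nclass; ++c) maxv = std::max(maxv, votes[c]);
      int ntied = 0, winner = -1;
      for (int c = 0; c < w.nclass; ++c) if (votes[c] == maxv) { ntied++; winner = c; }
      if (ntied > 1) {
        // tie: class of the single nearest neighbour among tied classes
        for (int a = 0; a < knn_k; ++a)
          if (votes[w.y[sel[a]]] == maxv) { winner = w.y[sel[a]]; break; }
      } else {
        for (int c = 0; c < w.nclass; ++c) if (votes[c] == maxv) { winner = c; break; }
      }
      pred[i] = winner;
    } else {  // PNN
      double sigma = (sigma_abs > 0) ? sigma_abs : sigma_mult * std::sqrt(rms2);
      double inv = (sigma > 0) ? 1.0 / (2.0 * sigma * sigma) : R_PosInf;
      std::fill(score.begin(), score.end(), 0.0);
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        score[w.y[j]] += std::exp(-d2[j] * inv);
      }
      int nearest = 0;
      double dmin = R_PosInf;
      for (int j = 0; j < n; ++j)
        if (j != i && d2[j] < dmin) { dmin = d2[j]; nearest = j; }
      double best = -1.0;
      int winner = -1, ntied = 0;
      for (int c = 0; c < w.nclass; ++c) {
        int nc = w.ccount[c] - (w.y[i] == c ? 1 : 0);
        if (nc <= 0) { score[c] = -1.0; continue; }
        score[c] /= nc;
        if (score[c] > best) { best = score[c]; winner = c; ntied = 1; }
        else if (score[c] == best) ntied++;
      }
      if (ntied > 1 || best <= 0.0) winner = w.y[nearest];
      pred[i] = winner;
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_loo_predict(NumericMatrix X, IntegerVector y, IntegerVector subset,
                              int method, int knn_k, double sigma_abs,
                              double sigma_mult) {
  LooWorkspace w = build_workspace(X, y);
  std::vector<int> fs(subset.begin(), subset.end());
  std::vector<int> pred;
  loo_predict_subset(w, fs, method, knn_k, sigma_abs, sigma_mult, pred);
  IntegerVector out(w.n);
  for (int i = 0; i < w.n; ++i) out[i] = pred[i];
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_loo_score_subsets(NumericMatrix X, IntegerVector y, List subsets,
                                    int method, int knn_k, double sigma_abs,
                                    double sigma_mult) {
  LooWorkspace w = build_workspace(X, y);
  int m = subsets.size();
  NumericVector acc(m);
  std::vector<int> pred;
  for (int s = 0; s < m; ++s) {
    IntegerVector sub = subsets[s];
    std::vector<int> fs(sub.begin(), sub.end());
    loo_predict_subset(w, fs, method, knn_k, sigma_abs, sigma_mult, pred);
    int ok = 0;
    for (int i = 0; i < w.n; ++i) if (pred[i] == w.y[i]) ok++;
    acc[s] = (double)ok / w.n;
    if (s % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return acc;
}
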