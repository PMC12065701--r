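// Inner loops of the pipeline: weighted kNN, stochastic-gradient NCA and the
// INCA prefix-size loss scan.  All tie and zero-distance rules are fixed and
// deterministic: neighbour ties at the k-th position keep the first k in
// stable index order; class-score ties predict class 1; any zero-distance
// neighbour switches the vote to a majority among zero-distance neighbours.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>

using namespace Rcpp;

static void knn_predict_row(const double* dist, const int* trainy, int ntrain,
                            int k, int& pred, double& score1) {
  std::vector<int> idx(ntrain);
  std::iota(idx.begin(), idx.end(), 0);
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return dist[a] < dist[b]; });
  int nzero = 0, z1 = 0;
  for (int j = 0; j < k; ++j) {
    if (dist[idx[j]] == 0.0) {
      ++nzero;
      if (trainy[idx[j]] == 1) ++z1;
    }
  }
  if (nzero > 0) { // squared-inverse limit: zero-distance neighbours dominate
    score1 = (double)z1 / nzero;
    pred = (2 * z1 >= nzero) ? 1 : 2;
    return;
  }
  double w1 = 0.0, w2 = 0.0;
  for (int j = 0; j < k; ++j) {
    double d = dist[idx[j]];
    double w = 1.0 / (d * d);
    if (trainy[idx[j]] == 1) w1 += w; else w2 += w;
  }
  score1 = w1 / (w1 + w2);
  pred = (w1 >= w2) ? 1 : 2;
}

// [[Rcpp::export(name = ".knn_weighted_cpp")]]
List knn_weighted_cpp(NumericMatrix train, IntegerVector trainy,
                      NumericMatrix test, int k) {
  const int ntrain = train.nrow(), ntest = test.nrow(), d = train.ncol();
  IntegerVector pred(ntest);
  NumericVector score1(ntest);
  std::vector<double> dist(ntrain);
  for (int i = 0; i < ntest; ++i) {
    for (int j = 0; j < ntrain; ++j) {
      double s = 0.0;
      for (int r = 0; r < d; ++r) s += std::abs(test(i, r) - train(j, r));
      dist[j] = s;
    }
    int p; double sc;
    knn_predict_row(dist.data(), trainy.begin(), ntrain, k, p, sc);
    pred[i] = p;
    score1[i] = sc;
  }
  return List::create(_["pred"] = pred, _["score1"] = score1);
}

// Neighbourhood component analysis for feature weighting (NCFS-style):
// distance d_w(i, j) = sum_r w_r^2 |x_ir - x_jr|; per-sample objective
// p_i - lambda * sum w_r^2 with p_i the leave-one-out probability of a
// same-class reference point under the softmax kernel exp(-d / sigma).
// One SGD update per visited sample; `order` supplies the full visiting
// sequence (R-side RNG), 0-based.
// [[Rcpp::export(name = ".nca_sgd_cpp")]]
NumericVector nca_sgd_cpp(NumericMatrix Xt, IntegerVector y,
                          IntegerVector order, double lambda, double sigma,
                          double alpha0) {
  // Xt is the transposed d x n data: one contiguous column per sample
  const int d = Xt.nrow(), n = Xt.ncol();
  const double* X = Xt.begin();
  NumericVector w(d, 1.0);
  std::vector<double> dist(n), p(n), s_all(d), s_same(d), w2(d);
  std::vector<double> absrow((size_t)n * d);
  const int total = order.size();
  for (int t = 0; t < total; ++t) {
    const int i = order[t];
    const double* xi = X + (size_t)i * d;
    for (int r = 0; r < d; ++r) w2[r] = w[r] * w[r];
    // distances from i under current weights, cache |x_i - x_j| per feature
    double dmin = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i) { dist[j] = R_PosInf; continue; }
      double s = 0.0;
      double* arow = &absrow[(size_t)j * d];
      const double* xj = X + (size_t)j * d;
      for (int r = 0; r < d; ++r) {
        double a = std::abs(xi[r] - xj[r]);
        arow[r] = a;
        s += w2[r] * a;
      }
      dist[j] = s;
      if (s < dmin) dmin = s;
    }
    double z = 0.0;
    for (int j = 0; j < n; ++j) {
      p[j] = (j == i) ? 0.0 : std::exp(-(dist[j] - dmin) / sigma);
      z += p[j];
    }
    if (z <= 0.0) continue;
    double pi = 0.0;
    for (int j = 0; j < n; ++j) {
      p[j] /= z;
      if (j != i && y[j] == y[i]) pi += p[j];
    }
    std::fill(s_all.begin(), s_all.end(), 0.0);
    std::fill(s_same.begin(), s_same.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      if (j == i || p[j] == 0.0) continue;
      const double pj = p[j];
      const double* arow = &absrow[(size_t)j * d];
      const bool same = (y[j] == y[i]);
      for (int r = 0; r < d; ++r) {
        const double v = pj * arow[r];
        s_all[r] += v;
        if (same) s_same[r] += v;
      }
    }
    const double alpha = alpha0 * n / (n + t);
    for (int r = 0; r < d; ++r) {
      const double grad =
          2.0 * w[r] * ((pi * s_all[r] - s_same[r]) / sigma - lambda);
      w[r] += alpha * grad;
    }
  }
  return w;
}

// INCA scorer: misclassification rate of the weighted kNN for every prefix
// size of the (already rank-ordered) feature columns, under a fixed fold
// assignment.  Distances are accumulated incrementally across prefix sizes.
// [[Rcpp::export(name = ".inca_scan_cpp")]]
NumericVector inca_scan_cpp(NumericMatrix X, IntegerVector y,
                            IntegerVector sizes, IntegerVector foldid,
                            int k) {
  const int n = X.nrow();
  const int ns = sizes.size();
  const int nfold = *std::max_element(foldid.begin(), foldid.end());
  std::vector<int> errors(ns, 0);
  for (int f = 1; f <= nfold; ++f) {
    std::vector<int> te, tr;
    for (int i = 0; i < n; ++i) (foldid[i] == f ? te : tr).push_back(i);
    if (te.empty() || tr.empty()) continue;
    const int ntest = te.size(), ntrain = tr.size();
    const int keff = std::min(k, ntrain);
    std::vector<int> try_(ntrain);
    for (int j = 0; j < ntrain; ++j) try_[j] = y[tr[j]];
    std::vector<double> D((size_t)ntest * ntrain, 0.0);
    int col = 0;
    for (int s = 0; s < ns; ++s) {
      const int upto = sizes[s];
      for (; col < upto; ++col) {
        for (int a = 0; a < ntest; ++a) {
          const double xa = X(te[a], col);
          double* drow = &D[(size_t)a * ntrain];
          for (int b = 0; b < ntrain; ++b) {
            drow[b] += std::abs(xa - X(tr[b], col));
          }
        }
      }
      for (int a = 0; a < ntest; ++a) {
        int pred; double sc;
        knn_predict_row(&D[(size_t)a * ntrain], try_.data(), ntrain, keff,
                        pred, sc);
        if (pred != y[te[a]]) ++errors[s];
      }
    }
  }
  NumericVector mcr(ns);
  for (int s = 0; s < ns; ++s) mcr[s] = (double)errors[s] / n;
  return mcr;
}
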