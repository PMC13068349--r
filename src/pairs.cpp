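#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Copy the p x n column-major matrix into a point-contiguous layout
// (coordinates of one point adjacent in memory) for cache-friendly pair
// distance evaluation.
static std::vector<double> transpose_points(const NumericMatrix& X) {
  const int p = X.nrow(), n = X.ncol();
  std::vector<double> xt((size_t)p * n);
  const double* x = REAL(X);
  for (int c = 0; c < n; ++c)
    for (int i = 0; i < p; ++i)
      xt[(size_t)i * n + c] = x[i + (R_xlen_t)c * p];
  return xt;
}

static inline double pair_dist2(const double* xt, int n, int i, int j) {
  const double* a = xt + (size_t)i * n;
  const double* b = xt + (size_t)j * n;
  double s = 0.0;
  for (int c = 0; c < n; ++c) {
    double d = a[c] - b[c];
    s += d * d;
  }
  return s;
}

// Cumulative pair counts at each radius: counts[k] = #{pairs with dist <= radii[k]}.
// Exact enumeration of all P(P-1)/2 pairs when their number is <= max_pairs,
// otherwise a uniform random subsample of max_pairs pairs (uses R's RNG, so the
// caller controls reproducibility through set.seed()). Also returns the maximum
// distance seen and the number of pairs used.
// [[Rcpp::export]]
List cpp_pair_counts(NumericMatrix X, NumericVector radii, double max_pairs) {
  const int p = X.nrow(), n = X.ncol(), m = radii.size();
  std::vector<double> xt = transpose_points(X);
  std::vector<double> r2(m);          // compare squared distances: no sqrt per pair
  for (int k = 0; k < m; ++k) r2[k] = radii[k] * radii[k];
  const double* r = r2.data();
  std::vector<double> bins(m + 1, 0.0);
  double dmax = 0.0;
  const double npairs_total = (double)p * (p - 1) / 2.0;
  double used;

  if (npairs_total <= max_pairs) {
    used = npairs_total;
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        double d = pair_dist2(xt.data(), n, i, j);
        if (d > dmax) dmax = d;
        int idx = std::lower_bound(r, r + m, d) - r; // first radius >= d
        bins[idx] += 1.0;
      }
    }
  } else {
    R_xlen_t ns = (R_xlen_t)max_pairs;
    used = (double)ns;
    GetRNGstate();
    for (R_xlen_t s = 0; s < ns; ++s) {
      int i = (int)(unif_rand() * p);
      int j = (int)(unif_rand() * p);
      if (i >= p) i = p - 1;
      if (j >= p) j = p - 1;
      if (i == j) { --s; continue; }
      double d = pair_dist2(xt.data(), n, i, j);
      if (d > dmax) dmax = d;
      int idx = std::lower_bound(r, r + m, d) - r;
      bins[idx] += 1.0;
    }
    PutRNGstate();
  }
  NumericVector counts(m);
  double acc = 0.0;
  for (int k = 0; k < m; ++k) {
    acc += bins[k];
    counts[k] = acc;
  }
  return List::create(_["counts"] = counts, _["n_pairs"] = used,
                      _["max_dist"] = std::sqrt(dmax));
}

// Distances of a random subsample of pairs (for quantile-based radius grids).
// [[Rcpp::export]]
NumericVector cpp_pair_sample(NumericMatrix X, int n_sample) {
  const int p = X.nrow(), n = X.ncol();
  std::vector<double> xt = transpose_points(X);
  const double npairs_total = (double)p * (p - 1) / 2.0;
  if (npairs_total <= (double)n_sample) {
    R_xlen_t np = (R_xlen_t)npairs_total;
    NumericVector out(np);
    R_xlen_t s = 0;
    for (int i = 0; i < p - 1; ++i)
      for (int j = i + 1; j < p; ++j)
        out[s++] = std::sqrt(pair_dist2(xt.data(), n, i, j));
    return out;
  }
  NumericVector out(n_sample);
  GetRNGstate();
  for (int s = 0; s < n_sample; ++s) {
    int i = (int)(unif_rand() * p);
    int j = (int)(unif_rand() * p);
    if (i >= p) i = p - 1;
    if (j >= p) j = p - 1;
    if (i == j) { --s; continue; }
    out[s] = std::sqrt(pair_dist2(xt.data(), n, i, j));
  }
  PutRNGstate();
  return out;
}

// Nearest-neighbour distance within X for each row index in `subset` (1-based).
// [[Rcpp::export]]
NumericVector cpp_nn_dists(NumericMatrix X, IntegerVector subset) {
  const int p = X.nrow(), n = X.ncol(), m = subset.size();
  std::vector<double> xt = transpose_points(X);
  NumericVector out(m);
  for (int s = 0; s < m; ++s) {
    int i = subset[s] - 1;
    double best = R_PosInf;
    for (int j = 0; j < p; ++j) {
      if (j == i) continue;
      double d = pair_dist2(xt.data(), n, i, j);
      if (d < best) best = d;
    }
    out[s] = std::sqrt(best);
  }
  return out;
}

// Sorted distances to the k nearest neighbours of every row (self excluded).
// Returns a P x k matrix.
// [[Rcpp::export]]
NumericMatrix cpp_knn_dists(NumericMatrix X, int k) {
  const int p = X.nrow(), n = X.ncol();
  std::vector<double> xt = transpose_points(X);
  if (k >= p) stop("k must be smaller than the number of points");
  NumericMatrix out(p, k);
  std::vector<double> row(p - 1);
  for (int i = 0; i < p; ++i) {
    int c = 0;
    for (int j = 0; j < p; ++j) {
      if (j == i) continue;
      row[c++] = pair_dist2(xt.data(), n, i, j);
    }
    std::partial_sort(row.begin(), row.begin() + k, row.end());
    for (int q = 0; q < k; ++q) out(i, q) = std::sqrt(row[q]);
  }
  return out;
}
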