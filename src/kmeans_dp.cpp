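#include <Rcpp.h>
using namespace Rcpp;

// Globally WCSS-optimal partition of sorted 1-D data into k contiguous
// segments, by dynamic programming. An optimal k-means partition of 1-D data
// is always contiguous in sorted order, so this solves 1-D k-means exactly.
// Weights support the binned-histogram mode (each distinct value carries a
// count); for raw-voxel mode all weights are 1.
//
// cost(j, i): weighted SSQ of segment x[j..i] via prefix sums,
//   ssq = sum(w x^2) - (sum(w x))^2 / sum(w)
//
// Complexity O(k n^2) time, O(k n) space; n here is the number of distinct
// sorted values, comfortably small for PET lesion VOIs.

// [[Rcpp::export(name = ".kmeans_dp_cpp")]]
List kmeans_dp_cpp(NumericVector x, NumericVector w, int k) {
  const int n = x.size();
  if (k < 1 || k > n) stop("k must be in 1..n");

  std::vector<long double> cw(n + 1, 0.0), cwx(n + 1, 0.0), cwxx(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cw[i + 1]   = cw[i] + w[i];
    cwx[i + 1]  = cwx[i] + w[i] * x[i];
    cwxx[i + 1] = cwxx[i] + w[i] * x[i] * x[i];
  }
  auto cost = [&](int j, int i) -> long double {  // segment x[j..i], 0-based inclusive
    long double sw  = cw[i + 1] - cw[j];
    long double swx = cwx[i + 1] - cwx[j];
    long double ssq = cwxx[i + 1] - cwxx[j] - swx * swx / sw;
    return ssq > 0 ? ssq : 0.0;                   // guard tiny negative round-off
  };

  const long double INF = std::numeric_limits<long double>::infinity();
  // D[m][i]: optimal cost of first i+1 points in m+1 clusters; B[m][i]: start of last segment
  std::vector<std::vector<long double>> D(k, std::vector<long double>(n, INF));
  std::vector<std::vector<int>> B(k, std::vector<int>(n, 0));
  for (int i = 0; i < n; ++i) D[0][i] = cost(0, i);
  for (int m = 1; m < k; ++m) {
    for (int i = m; i < n; ++i) {
      for (int j = m; j <= i; ++j) {
        long double c = D[m - 1][j - 1] + cost(j, i);
        if (c < D[m][i]) { D[m][i] = c; B[m][i] = j; }
      }
    }
  }

  IntegerVector labels(n);
  NumericVector centroids(k), sizes(k);
  int hi = n - 1;
  for (int m = k - 1; m >= 0; --m) {
    int lo = (m == 0) ? 0 : B[m][hi];
    long double sw = cw[hi + 1] - cw[lo], swx = cwx[hi + 1] - cwx[lo];
    centroids[m] = (double)(swx / sw);
    sizes[m] = (double)sw;
    for (int i = lo; i <= hi; ++i) labels[i] = m;  // 0-based cluster ids, ascending
    hi = lo - 1;
  }

  return List::create(_["labels"] = labels,
                      _["centroids"] = centroids,
                      _["sizes"] = sizes,
                      _["wcss"] = (double)D[k - 1][n - 1]);
}
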