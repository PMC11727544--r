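#include <Rcpp.h>
using namespace Rcpp;

// Minimum-average-direct-flip (MDF) distances between two sets of
// streamlines, each resampled to a common number of points and flattened
// row-wise as (x1, y1, z1, x2, y2, z2, ...).  The MDF between two
// streamlines is the smaller of the mean pointwise Euclidean distance in
// direct point order and in reversed order, which makes the metric
// invariant to the (arbitrary) direction in which a streamline was tracked.

// [[Rcpp::export(name = ".mdf_cross_cpp")]]
NumericMatrix mdf_cross_cpp(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  if (A.ncol() != B.ncol())
    stop("point counts differ between the two sets");
  if (A.ncol() % 3 != 0)
    stop("rows must be flattened xyz triples");
  const int k = A.ncol() / 3;
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    const double *a = &A(i, 0);
    for (int j = 0; j < m; ++j) {
      const double *b = &B(j, 0);
      double dir = 0.0, flip = 0.0;
      for (int p = 0; p < k; ++p) {
        // column-major storage: element (i, 3*p+c) lives at a[(3*p+c)*n]
        const double ax = a[(3 * p) * n];
        const double ay = a[(3 * p + 1) * n];
        const double az = a[(3 * p + 2) * n];
        const int q = k - 1 - p;
        double dx = ax - b[(3 * p) * m];
        double dy = ay - b[(3 * p + 1) * m];
        double dz = az - b[(3 * p + 2) * m];
        dir += std::sqrt(dx * dx + dy * dy + dz * dz);
        dx = ax - b[(3 * q) * m];
        dy = ay - b[(3 * q + 1) * m];
        dz = az - b[(3 * q + 2) * m];
        flip += std::sqrt(dx * dx + dy * dy + dz * dz);
      }
      D(i, j) = std::min(dir, flip) / k;
    }
  }
  return D;
}
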