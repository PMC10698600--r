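// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb-Huttenlocher lower-envelope passes along each axis).
// Returns, for every voxel, the squared distance in mm^2 to the nearest
// zero voxel of the input mask.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n,
                 double w) {
  // w = spacing along this axis; sample i sits at position i*w
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      const int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(const IntegerVector& mask, const IntegerVector& dims,
                         const NumericVector& spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  const double INF = 1e30;
  NumericVector D(n);
  for (R_xlen_t v = 0; v < n; ++v) D[v] = mask[v] != 0 ? INF : 0.0;
  const int mx = std::max(n1, std::max(n2, n3));
  std::vector<double> f(mx), d(mx);
  // axis 1
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = D[base + i];
      dt1d(f, d, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) D[base + i] = d[i];
    }
  // axis 2
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j)
        f[j] = D[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(f, d, n2, spacing[1]);
      for (int j = 0; j < n2; ++j)
        D[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = d[j];
    }
  // axis 3
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k)
        f[k] = D[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
      dt1d(f, d, n3, spacing[2]);
      for (int k = 0; k < n3; ++k)
        D[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)] = d[k];
    }
  return D;
}
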