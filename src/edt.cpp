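#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform of one scanline
// (lower-envelope-of-parabolas algorithm), with physical sample spacing w.
// f: squared distances on entry, overwritten with the transformed values.
static void dt1d(std::vector<double> &f, double w) {
  const int n = (int)f.size();
  if (n == 1) return;
  // "unreachable" is encoded as a large finite value so the envelope
  // arithmetic below never produces NaN (Inf - Inf)
  static const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
               (2.0 * w * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < w * q) ++j;
    double dq = w * (q - v[j]);
    d[q] = dq * dq + f[v[j]];
  }
  f.swap(d);
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector mask, IntegerVector dims,
                        NumericVector spacing) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double BIG = 1e30;  // finite stand-in for "no site on this line yet"
  NumericVector out(mask.size());
  // squared distance to nearest zero voxel; zero voxels are sites (0)
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? BIG : 0.0;

  std::vector<double> line;
  // pass along axis 1 (fastest varying index)
  line.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; ++i) line[i] = out[base + i];
      dt1d(line, spacing[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = line[i];
    }
  // pass along axis 2
  line.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; ++j) line[j] = out[base + (R_xlen_t)j * n1];
      dt1d(line, spacing[1]);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)j * n1] = line[j];
    }
  // pass along axis 3
  line.resize(n3);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      R_xlen_t stride = (R_xlen_t)n1 * n2;
      for (int k = 0; k < n3; ++k) line[k] = out[base + k * stride];
      dt1d(line, spacing[2]);
      for (int k = 0; k < n3; ++k) out[base + k * stride] = line[k];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i)
    out[i] = std::sqrt(out[i]);
  return out;
}
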