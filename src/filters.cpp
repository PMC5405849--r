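#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Half-sample symmetric ("reflect") boundary index: d c b a | a b c d | d c b a.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// Correlate a 3D grid (R column-major, dim = (d0, d1, d2)) with a centred 1D
// kernel along one axis. Kernel length must be odd.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector v, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  const int klen = kernel.size();
  const int khalf = klen / 2;
  NumericVector out(v.size());

  const R_xlen_t s0 = 1, s1 = (R_xlen_t)d0, s2 = (R_xlen_t)d0 * d1;
  R_xlen_t stride;
  int n, da, db;
  R_xlen_t sa, sb;
  if (axis == 0)      { n = d0; stride = s0; da = d1; sa = s1; db = d2; sb = s2; }
  else if (axis == 1) { n = d1; stride = s1; da = d0; sa = s0; db = d2; sb = s2; }
  else                { n = d2; stride = s2; da = d0; sa = s0; db = d1; sb = s1; }

  std::vector<double> line(n);
  for (int ib = 0; ib < db; ++ib) {
    for (int ia = 0; ia < da; ++ia) {
      const R_xlen_t base = (R_xlen_t)ia * sa + (R_xlen_t)ib * sb;
      for (int i = 0; i < n; ++i) line[i] = v[base + (R_xlen_t)i * stride];
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int k = 0; k < klen; ++k) {
          int j = reflect_idx(i + k - khalf, n);
          acc += kernel[k] * line[j];
        }
        out[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}

// Eigenvalues of many symmetric 3x3 matrices, sorted descending by signed
// value. Uses the trigonometric closed form for symmetric matrices.
// [[Rcpp::export]]
NumericMatrix cpp_sym3_eigenvalues(NumericVector a11, NumericVector a12,
                                   NumericVector a13, NumericVector a22,
                                   NumericVector a23, NumericVector a33) {
  const R_xlen_t m = a11.size();
  NumericMatrix out(m, 3);
  for (R_xlen_t i = 0; i < m; ++i) {
    double a = a11[i], b = a12[i], c = a13[i], d = a22[i], e = a23[i], f = a33[i];
    double e1, e2, e3;
    double p1 = b * b + c * c + e * e;
    if (p1 == 0.0) {
      e1 = a; e2 = d; e3 = f;
    } else {
      double q = (a + d + f) / 3.0;
      double p2 = (a - q) * (a - q) + (d - q) * (d - q) + (f - q) * (f - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // B = (A - qI) / p; r = det(B) / 2
      double b11 = (a - q) / p, b22 = (d - q) / p, b33 = (f - q) / p;
      double b12 = b / p, b13 = c / p, b23 = e / p;
      double detB = b11 * (b22 * b33 - b23 * b23)
                  - b12 * (b12 * b33 - b23 * b13)
                  + b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0;
      if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    // sort descending
    if (e1 < e2) std::swap(e1, e2);
    if (e2 < e3) std::swap(e2, e3);
    if (e1 < e2) std::swap(e1, e2);
    out(i, 0) = e1; out(i, 1) = e2; out(i, 2) = e3;
  }
  return out;
}
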