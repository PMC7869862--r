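#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform on an anisotropic grid
// (Felzenszwalb & Huttenlocher lower-envelope scan per axis), with
// propagation of the nearest-site linear index ("feature transform").
// Arrays are R-order with z fastest: linear = z + nz*(y + ny*x).

static const double VC_INF = 1e30;

// One 1-D pass along an axis with stride `stride`, `n` samples, squared
// spacing w2. f: squared distances in/out; feat: nearest-site indices in/out.
static void dt1d(std::vector<double>& f, std::vector<int>& src,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& d, int n, double w2) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
    src[q] = p;
  }
}

// [[Rcpp::export]]
List cpp_edt(LogicalVector site, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector d2(n);
  IntegerVector feat(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (site[i]) { d2[i] = 0.0; feat[i] = (int)i; }
    else { d2[i] = VC_INF; feat[i] = -1; }
  }
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), z(nmax + 1), dline(nmax);
  std::vector<int> v(nmax), src(nmax), fline(nmax);

  // axis order: z (stride 1), y (stride nz), x (stride nz*ny)
  const int ns[3] = { nz, ny, nx };
  const double w[3] = { spacing[0], spacing[1], spacing[2] };
  const R_xlen_t strides[3] = { 1, (R_xlen_t)nz, (R_xlen_t)nz * ny };
  for (int ax = 0; ax < 3; ++ax) {
    const int len = ns[ax];
    if (len == 1) continue;
    const double w2 = w[ax] * w[ax];
    const R_xlen_t st = strides[ax];
    // iterate over all lines orthogonal to ax
    const int oa = (ax == 0) ? 1 : 0;          // first other axis
    const int ob = (ax == 2) ? 1 : 2;          // second other axis
    const R_xlen_t sta = strides[oa], stb = strides[ob];
    for (int b = 0; b < ns[ob]; ++b) {
      for (int a = 0; a < ns[oa]; ++a) {
        const R_xlen_t base = a * sta + b * stb;
        for (int q = 0; q < len; ++q) f[q] = d2[base + q * st];
        dt1d(f, src, v, z, dline, len, w2);
        for (int q = 0; q < len; ++q) fline[q] = feat[base + src[q] * st];
        for (int q = 0; q < len; ++q) {
          d2[base + q * st] = dline[q];
          feat[base + q * st] = fline[q];
        }
      }
    }
  }
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (d2[i] >= 1e29) { dist[i] = R_PosInf; feat[i] = -1; }
    else dist[i] = std::sqrt(d2[i]);
  }
  return List::create(_["dist"] = dist, _["feat"] = feat);
}
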