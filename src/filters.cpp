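#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable Gaussian smoothing with reflect padding; sigma given in voxel
// units per axis (z, y, x); sigma <= 0 skips that axis.
// Layout: linear = z + nz*(y + ny*x).

static void conv1d(std::vector<double>& buf, std::vector<double>& out,
                   const std::vector<double>& k, int n, int r) {
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int j = -r; j <= r; ++j) {
      int p = i + j;
      if (p < 0) p = -p - 1;            // reflect
      else if (p >= n) p = 2 * n - p - 1;
      acc += buf[p] * k[j + r];
    }
    out[i] = acc;
  }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector x, IntegerVector dims,
                             NumericVector sigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out = clone(x);
  const int ns[3] = { nz, ny, nx };
  const R_xlen_t strides[3] = { 1, (R_xlen_t)nz, (R_xlen_t)nz * ny };
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> buf(nmax), res(nmax);
  for (int ax = 0; ax < 3; ++ax) {
    const double s = sigma[ax];
    if (s <= 0.0 || ns[ax] == 1) continue;
    const int r = (int)std::ceil(3.0 * s);
    std::vector<double> k(2 * r + 1);
    double ksum = 0.0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * j * j / (s * s));
      ksum += k[j + r];
    }
    for (double& v : k) v /= ksum;
    const int len = ns[ax];
    const R_xlen_t st = strides[ax];
    const int oa = (ax == 0) ? 1 : 0;
    const int ob = (ax == 2) ? 1 : 2;
    const R_xlen_t sta = strides[oa], stb = strides[ob];
    for (int b = 0; b < ns[ob]; ++b) {
      for (int a = 0; a < ns[oa]; ++a) {
        const R_xlen_t base = a * sta + b * stb;
        for (int q = 0; q < len; ++q) buf[q] = out[base + q * st];
        conv1d(buf, res, k, len, r);
        for (int q = 0; q < len; ++q) out[base + q * st] = res[q];
      }
    }
  }
  return out;
}

// 2-D hole filling applied slice by slice along z: background pixels of a
// slice not reachable (4-connectivity) from the slice border become
// foreground. Returns the filled mask.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  LogicalVector out = clone(mask);
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  std::vector<unsigned char> reach((size_t)ny * nx);
  std::vector<int> stack;
  stack.reserve((size_t)ny * nx);
  for (int z = 0; z < nz; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    stack.clear();
    // seed: border background pixels
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        if (y != 0 && y != ny - 1 && x != 0 && x != nx - 1) continue;
        const R_xlen_t idx = z + sy * y + sx * x;
        if (!out[idx]) { reach[y + (size_t)ny * x] = 1; stack.push_back(y + ny * x); }
      }
    }
    while (!stack.empty()) {
      const int p = stack.back(); stack.pop_back();
      const int y = p % ny, x = p / ny;
      const int dy[4] = { -1, 1, 0, 0 }, dx[4] = { 0, 0, -1, 1 };
      for (int q = 0; q < 4; ++q) {
        const int yy = y + dy[q], xx = x + dx[q];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        const size_t rp = yy + (size_t)ny * xx;
        if (reach[rp]) continue;
        if (out[z + sy * yy + sx * xx]) continue;
        reach[rp] = 1;
        stack.push_back(yy + ny * xx);
      }
    }
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t idx = z + sy * y + sx * x;
        if (!out[idx] && !reach[y + (size_t)ny * x]) out[idx] = TRUE;
      }
  }
  return out;
}
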