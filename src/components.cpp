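#include <Rcpp.h>
#include <vector>
#include <queue>
#include <tuple>
#include <cmath>
using namespace Rcpp;

// Layout: linear = z + nz*(y + ny*x).

static void neighbor_offsets(int connectivity, std::vector<int>& dz,
                             std::vector<int>& dy, std::vector<int>& dx) {
  dz.clear(); dy.clear(); dx.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        const int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// Connected-component labeling of a binary mask. Labels are assigned in
// raster-scan discovery order (1..N); callers relabel as needed.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> dz, dy, dx;
  neighbor_offsets(connectivity, dz, dy, dx);
  const int nn = (int)dz.size();
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t p = stack.back(); stack.pop_back();
      const int z = (int)(p % nz);
      const int y = (int)((p / nz) % ny);
      const int x = (int)(p / ((R_xlen_t)nz * ny));
      for (int q = 0; q < nn; ++q) {
        const int zz = z + dz[q], yy = y + dy[q], xx = x + dx[q];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        const R_xlen_t pp = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (!mask[pp] || lab[pp] != 0) continue;
        lab[pp] = next;
        stack.push_back(pp);
      }
    }
  }
  return lab;
}

// Strict-or-equal local maxima of `value` restricted to `mask` (26-neighborhood):
// a voxel is a maximum when no neighbor in the mask has a larger value.
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector value, LogicalVector mask,
                               IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n, FALSE);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    const int z = (int)(i % nz);
    const int y = (int)((i / nz) % ny);
    const int x = (int)(i / ((R_xlen_t)nz * ny));
    bool ok = true;
    for (int a = -1; a <= 1 && ok; ++a)
      for (int b = -1; b <= 1 && ok; ++b)
        for (int c = -1; c <= 1 && ok; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          const int zz = z + a, yy = y + b, xx = x + c;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          const R_xlen_t pp = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (mask[pp] && value[pp] > value[i]) ok = false;
        }
    if (ok) out[i] = TRUE;
  }
  return out;
}

// Marker-based watershed by priority flooding: grow markers over `mask`
// in order of decreasing `priority` (here: the interior distance map).
// Ties resolved by insertion order, making the result deterministic.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector priority, LogicalVector mask,
                            IntegerVector markers, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  typedef std::tuple<double, R_xlen_t, R_xlen_t> Item; // (-prio, order, idx)
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  R_xlen_t order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Item(-priority[i], order++, i));
    }
  }
  while (!pq.empty()) {
    const R_xlen_t p = std::get<2>(pq.top());
    pq.pop();
    const int z = (int)(p % nz);
    const int y = (int)((p / nz) % ny);
    const int x = (int)(p / ((R_xlen_t)nz * ny));
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          const int zz = z + a, yy = y + b, xx = x + c;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          const R_xlen_t pp = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (!mask[pp] || lab[pp] != 0) continue;
          lab[pp] = lab[p];
          pq.push(Item(-priority[pp], order++, pp));
        }
  }
  return lab;
}
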