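#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Arrays arrive column-major with dim = (nz, ny, nx); linear index
// i = z + nz*(y + ny*x). All kernels are deterministic: scan order and
// explicit tie-breaking fix the output for identical input.

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// 3D connected-component labelling of a binary mask.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector ll_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);

  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dz, dy, dx});
      }

  int next = 0;
  std::vector<int> stack;
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (!mask[i] || lab[i] != 0) continue;
        lab[i] = ++next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          int cz = c % nz, rest = c / nz, cy = rest % ny, cx = rest / ny;
          for (const auto &o : offs) {
            int zz = cz + o[0], yy = cy + o[1], xx = cx + o[2];
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            int j = idx3(zz, yy, xx, nz, ny);
            if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &zb,
                  int n, double step) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qs = (double)q * step, s;
    for (;;) {
      double vs = (double)v[k] * step;
      s = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * (qs - vs));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = (double)q * step;
    while (zb[k + 1] < qs) ++k;
    double vs = (double)v[k] * step;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// Euclidean distance (physical units per `spacing` = (z,y,x) step sizes)
// from every true voxel of `mask` to the nearest false voxel.
// [[Rcpp::export]]
NumericVector ll_edt3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // large finite sentinel: keeps the lower-envelope intersection
  // arithmetic finite even when a whole scan line is foreground
  const double BIG = 1e30;
  R_xlen_t n = mask.size();
  std::vector<double> d(n);
  for (R_xlen_t i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;

  int maxdim = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxdim), dd(maxdim), zb(maxdim + 1);
  std::vector<int> v(maxdim);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) f[z] = d[idx3(z, y, x, nz, ny)];
      edt1d(f, dd, v, zb, nz, spacing[0]);
      for (int z = 0; z < nz; ++z) d[idx3(z, y, x, nz, ny)] = dd[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[idx3(z, y, x, nz, ny)];
      edt1d(f, dd, v, zb, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[idx3(z, y, x, nz, ny)] = dd[y];
    }
  // pass along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = d[idx3(z, y, x, nz, ny)];
      edt1d(f, dd, v, zb, nx, spacing[2]);
      for (int x = 0; x < nx; ++x) d[idx3(z, y, x, nz, ny)] = dd[x];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dims;
  return out;
}

struct WsNode {
  double prio;
  long long order;
  int index;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;   // lower priority first
    return a.order > b.order;                       // FIFO on ties
  }
};

// Seeded watershed by priority flooding: seeds (label > 0) grow into
// `mask` in order of increasing `prio` (pass -distance to grow ridges
// last). 6-connectivity growth keeps basins contiguous.
// [[Rcpp::export]]
IntegerVector ll_watershed3d(NumericVector prio, IntegerVector seeds,
                             LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  R_xlen_t n = prio.size();
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long counter = 0;

  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        int i = idx3(z, y, x, nz, ny);
        if (seeds[i] > 0 && mask[i]) {
          lab[i] = seeds[i];
          pq.push({prio[i], counter++, i});
        }
      }

  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int c = nd.index;
    int cz = c % nz, rest = c / nz, cy = rest % ny, cx = rest / ny;
    for (int k = 0; k < 6; ++k) {
      int zz = cz + dz[k], yy = cy + dy[k], xx = cx + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = lab[c];
      pq.push({prio[j], counter++, j});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
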