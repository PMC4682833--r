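#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Union-find with 2*pi-multiple potentials relative to the parent.
// find() returns the root and accumulates the node's total offset (in 2*pi
// units) into `off`.
struct UF {
  std::vector<int> parent, size;
  std::vector<long long> pot;  // offset of node relative to parent
  UF(int n) : parent(n), size(n, 1), pot(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x, long long &off) {
    long long acc = 0;
    int r = x;
    while (parent[r] != r) { acc += pot[r]; r = parent[r]; }
    // path compression with potential update
    int cur = x;
    long long rem = acc;
    while (parent[cur] != r) {
      int nxt = parent[cur];
      long long p = pot[cur];
      parent[cur] = r;
      pot[cur] = rem;
      rem -= p;
      cur = nxt;
    }
    off += acc;
    return r;
  }
};

// Best-pair-first region-merging phase unwrapping.
// Edges between 6-adjacent in-mask voxels are scored by mean boundary
// magnitude (higher = merged earlier); merging adds the integer 2*pi multiple
// that minimizes the phase step across the edge. Returns wrapped + 2*pi*k.
// [[Rcpp::export]]
NumericVector cpp_unwrap_region_merge(NumericVector wrapped, NumericVector quality,
                                      LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  struct Edge { float score; int a, b; };
  std::vector<Edge> edges;
  edges.reserve(3 * (size_t)n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = x + nx * (y + ny * z);
        if (!mask[i]) continue;
        if (x + 1 < nx && mask[i + 1])
          edges.push_back({(float)(0.5 * (quality[i] + quality[i + 1])), i, i + 1});
        if (y + 1 < ny && mask[i + nx])
          edges.push_back({(float)(0.5 * (quality[i] + quality[i + nx])), i, i + nx});
        if (z + 1 < nz && mask[i + nx * ny])
          edges.push_back({(float)(0.5 * (quality[i] + quality[i + nx * ny])), i, i + nx * ny});
      }
  // stable sort: highest score first, ties in construction (lexicographic) order
  std::stable_sort(edges.begin(), edges.end(),
                   [](const Edge &l, const Edge &r) { return l.score > r.score; });
  UF uf(n);
  const double twopi = 2.0 * M_PI;
  for (const Edge &e : edges) {
    long long oa = 0, ob = 0;
    int ra = uf.find(e.a, oa), rb = uf.find(e.b, ob);
    if (ra == rb) continue;
    double va = wrapped[e.a] + twopi * oa;
    double vb = wrapped[e.b] + twopi * ob;
    long long k = (long long)std::llround((va - vb) / twopi);
    // attach the smaller region under the larger; the attached region's root
    // potential shifts every one of its voxels by the same 2*pi multiple
    if (uf.size[ra] < uf.size[rb]) {
      uf.parent[ra] = rb;
      uf.pot[ra] = -k;  // region A shifts by -k so va - k*2pi ~ vb
      uf.size[rb] += uf.size[ra];
    } else {
      uf.parent[rb] = ra;
      uf.pot[rb] = k;   // region B shifts by +k so vb + k*2pi ~ va
      uf.size[ra] += uf.size[rb];
    }
  }
  NumericVector out(n, NA_REAL);
  for (int i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    long long o = 0;
    uf.find(i, o);
    out[i] = wrapped[i] + twopi * o;
  }
  out.attr("dim") = dims;
  return out;
}

// Connected-component labeling (6 or 26 connectivity), BFS, labels in
// column-major first-encounter order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ad != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cz = c / (nx * ny), cy = (c / nx) % ny, cx = c % nx;
      for (auto &o : offs) {
        int x = cx + o[0], y = cy + o[1], z = cz + o[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) continue;
        int j = x + nx * (y + ny * z);
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Iterated binary dilation (6 or 26 connectivity).
// [[Rcpp::export]]
LogicalVector cpp_binary_dilate(LogicalVector mask, int iterations, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (int i = 0; i < n; ++i) cur[i] = mask[i] ? 1 : 0;
  std::vector<std::array<int, 3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && ad != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  for (int it = 0; it < iterations; ++it) {
    nxt = cur;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = x + nx * (y + ny * z);
          if (cur[i]) continue;
          for (auto &o : offs) {
            int xx = x + o[0], yy = y + o[1], zz = z + o[2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            if (cur[xx + nx * (yy + ny * zz)]) { nxt[i] = 1; break; }
          }
        }
    std::swap(cur, nxt);
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dims;
  return out;
}
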