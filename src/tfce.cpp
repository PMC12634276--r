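#include <Rcpp.h>
using namespace Rcpp;

// union-find with component sizes
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, std::vector<int>& size,
                     int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a == b) return;
  if (size[a] < size[b]) std::swap(a, b);
  parent[b] = a;
  size[a] += size[b];
}

// TFCE over an arbitrary voxel subset of a 3D grid.
// heights: nonnegative statistic per mask voxel
// coords: n x 3 matrix of 0-based voxel coordinates
// dims: grid shape (3)
// E, H: extent and height exponents; dh: step (<= 0 -> max/n_steps)
// n_steps: number of integration steps when dh <= 0
// conn: 6, 18 or 26 neighbourhood
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector heights, IntegerMatrix coords,
                       IntegerVector dims, double E, double H,
                       double dh, int n_steps, int conn) {
  const int n = heights.size();
  NumericVector out(n);
  if (n == 0) return out;
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) if (heights[i] > hmax) hmax = heights[i];
  if (hmax <= 0.0) return out;
  if (dh <= 0.0) dh = hmax / n_steps;

  const int dx = dims[0], dy = dims[1], dz = dims[2];
  // linear index lookup: grid cell -> mask voxel id (or -1)
  std::vector<int> lut((size_t)dx * dy * dz, -1);
  for (int i = 0; i < n; ++i) {
    size_t lin = coords(i, 0) + (size_t)dx * (coords(i, 1) + (size_t)dy * coords(i, 2));
    lut[lin] = i;
  }

  // neighbour offsets for the requested connectivity
  std::vector<std::array<int, 3>> offs;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if ((conn == 6 && m > 1) || (conn == 18 && m > 2)) continue;
        offs.push_back({a, b, c});
      }

  // voxel ids sorted by descending height
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return heights[a] > heights[b]; });

  std::vector<int> parent(n), size(n, 1);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  int nthr = (int)std::floor(hmax / dh + 1e-12);
  int pos = 0;  // next voxel (in descending order) to activate
  for (int s = nthr; s >= 1; --s) {
    double h = s * dh;
    while (pos < n && heights[order[pos]] >= h - 1e-12) {
      int v = order[pos];
      active[v] = 1;
      for (auto& o : offs) {
        int cx = coords(v, 0) + o[0], cy = coords(v, 1) + o[1],
            cz = coords(v, 2) + o[2];
        if (cx < 0 || cy < 0 || cz < 0 || cx >= dx || cy >= dy || cz >= dz)
          continue;
        int w = lut[cx + (size_t)dx * (cy + (size_t)dy * cz)];
        if (w >= 0 && active[w]) uf_union(parent, size, v, w);
      }
      ++pos;
    }
    double hH = std::pow(h, H) * dh;
    for (int i = 0; i < pos; ++i) {
      int v = order[i];
      out[v] += std::pow((double)size[uf_find(parent, v)], E) * hH;
    }
  }
  return out;
}
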