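// 3D image primitives for lung segmentation: connected components,
// seeded region growing, ball morphology, in-plane hole filling and
// multi-source label growth. All operate on flat column-major arrays
// with dims (slice, row, column) and are fully deterministic.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Nbh {
  std::vector<int> dz, dy, dx;
  Nbh(int connectivity) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          int manh = std::abs(a) + std::abs(b) + std::abs(c);
          if (connectivity == 6 && manh != 1) continue;
          dz.push_back(a); dy.push_back(b); dx.push_back(c);
        }
  }
  size_t size() const { return dz.size(); }
};

static inline int flat(int z, int y, int x, int d1, int d2) {
  return z + d1 * (y + d2 * x);
}

// Label 26- or 6-connected components of a binary mask. Labels are
// assigned 1..K in raster order of each component's first voxel, so the
// result is deterministic.
// [[Rcpp::export]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim, int connectivity = 26) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  IntegerVector labels(n, 0);
  Nbh nb(connectivity);
  int next = 0;
  std::queue<int> q;
  for (int x = 0; x < d3; ++x)
    for (int y = 0; y < d2; ++y)
      for (int z = 0; z < d1; ++z) {
        int i = flat(z, y, x, d1, d2);
        if (!mask[i] || labels[i]) continue;
        ++next;
        labels[i] = next;
        q.push(i);
        while (!q.empty()) {
          int j = q.front(); q.pop();
          int jz = j % d1, jy = (j / d1) % d2, jx = j / (d1 * d2);
          for (size_t k = 0; k < nb.size(); ++k) {
            int nz = jz + nb.dz[k], ny = jy + nb.dy[k], nx = jx + nb.dx[k];
            if (nz < 0 || nz >= d1 || ny < 0 || ny >= d2 || nx < 0 || nx >= d3) continue;
            int m = flat(nz, ny, nx, d1, d2);
            if (mask[m] && !labels[m]) { labels[m] = next; q.push(m); }
          }
        }
      }
  return labels;
}

// Grow from a 0-based seed index over voxels strictly below `threshold`.
// Returns a logical mask; empty if the seed itself is not below threshold.
// [[Rcpp::export]]
LogicalVector region_grow_3d(NumericVector values, IntegerVector dim, int seed,
                             double threshold, int connectivity = 6) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  LogicalVector out(n, false);
  if (seed < 0 || seed >= n || !(values[seed] < threshold)) return out;
  Nbh nb(connectivity);
  std::queue<int> q;
  out[seed] = true;
  q.push(seed);
  while (!q.empty()) {
    int j = q.front(); q.pop();
    int jz = j % d1, jy = (j / d1) % d2, jx = j / (d1 * d2);
    for (size_t k = 0; k < nb.size(); ++k) {
      int nz = jz + nb.dz[k], ny = jy + nb.dy[k], nx = jx + nb.dx[k];
      if (nz < 0 || nz >= d1 || ny < 0 || ny >= d2 || nx < 0 || nx >= d3) continue;
      int m = flat(nz, ny, nx, d1, d2);
      if (!out[m] && values[m] < threshold) { out[m] = true; q.push(m); }
    }
  }
  return out;
}

// Dilate by an explicit offset set (rows of `offsets` are voxel deltas
// (dz, dy, dx)); out-of-bounds targets are dropped.
// [[Rcpp::export]]
LogicalVector dilate_3d(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  LogicalVector out(n, false);
  int no = offsets.nrow();
  for (int x = 0; x < d3; ++x)
    for (int y = 0; y < d2; ++y)
      for (int z = 0; z < d1; ++z) {
        int i = flat(z, y, x, d1, d2);
        if (!mask[i]) continue;
        for (int k = 0; k < no; ++k) {
          int nz = z + offsets(k, 0), ny = y + offsets(k, 1), nx = x + offsets(k, 2);
          if (nz < 0 || nz >= d1 || ny < 0 || ny >= d2 || nx < 0 || nx >= d3) continue;
          out[flat(nz, ny, nx, d1, d2)] = true;
        }
      }
  return out;
}

// Erode by an offset set: a voxel survives if all offset neighbours are in
// the mask (outside the grid counts as background).
// [[Rcpp::export]]
LogicalVector erode_3d(LogicalVector mask, IntegerVector dim, IntegerMatrix offsets) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  LogicalVector out(n, false);
  int no = offsets.nrow();
  for (int x = 0; x < d3; ++x)
    for (int y = 0; y < d2; ++y)
      for (int z = 0; z < d1; ++z) {
        int i = flat(z, y, x, d1, d2);
        if (!mask[i]) continue;
        bool keep = true;
        for (int k = 0; k < no && keep; ++k) {
          int nz = z + offsets(k, 0), ny = y + offsets(k, 1), nx = x + offsets(k, 2);
          if (nz < 0 || nz >= d1 || ny < 0 || ny >= d2 || nx < 0 || nx >= d3) { keep = false; break; }
          if (!mask[flat(nz, ny, nx, d1, d2)]) keep = false;
        }
        if (keep) out[i] = true;
      }
  return out;
}

// Fill holes slice-by-slice: background 4-connected to the slice border is
// kept, every other non-mask voxel becomes mask.
// [[Rcpp::export]]
LogicalVector fill_holes_slicewise(LogicalVector mask, IntegerVector dim) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> reach((size_t)d2 * d3);
  const int dy[4] = {1, -1, 0, 0}, dx[4] = {0, 0, 1, -1};
  for (int z = 0; z < d1; ++z) {
    std::fill(reach.begin(), reach.end(), 0);
    std::queue<std::pair<int, int> > q;
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d3; ++x) {
        bool border = (y == 0 || y == d2 - 1 || x == 0 || x == d3 - 1);
        if (border && !mask[flat(z, y, x, d1, d2)] && !reach[y + (size_t)d2 * x]) {
          reach[y + (size_t)d2 * x] = 1;
          q.push(std::make_pair(y, x));
        }
      }
    while (!q.empty()) {
      std::pair<int, int> p = q.front(); q.pop();
      for (int k = 0; k < 4; ++k) {
        int ny = p.first + dy[k], nx = p.second + dx[k];
        if (ny < 0 || ny >= d2 || nx < 0 || nx >= d3) continue;
        if (reach[ny + (size_t)d2 * nx]) continue;
        if (mask[flat(z, ny, nx, d1, d2)]) continue;
        reach[ny + (size_t)d2 * nx] = 1;
        q.push(std::make_pair(ny, nx));
      }
    }
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d3; ++x)
        if (!mask[flat(z, y, x, d1, d2)] && !reach[y + (size_t)d2 * x])
          out[flat(z, y, x, d1, d2)] = true;
  }
  return out;
}

// Breadth-first multi-source label growth restricted to `mask`. Seeds carry
// labels > 0; remaining mask voxels take the label of the nearest seed in
// BFS (geodesic) distance. Lower labels are enqueued first, so equidistant
// voxels deterministically take the lower label.
// [[Rcpp::export]]
IntegerVector grow_labels_3d(IntegerVector seeds, LogicalVector mask, IntegerVector dim,
                             int connectivity = 6) {
  int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n = d1 * d2 * d3;
  IntegerVector out(n, 0);
  Nbh nb(connectivity);
  int maxlab = 0;
  for (int i = 0; i < n; ++i) if (seeds[i] > maxlab) maxlab = seeds[i];
  std::queue<int> q;
  for (int lab = 1; lab <= maxlab; ++lab)
    for (int x = 0; x < d3; ++x)
      for (int y = 0; y < d2; ++y)
        for (int z = 0; z < d1; ++z) {
          int i = flat(z, y, x, d1, d2);
          if (seeds[i] == lab && mask[i]) { out[i] = lab; q.push(i); }
        }
  while (!q.empty()) {
    int j = q.front(); q.pop();
    int jz = j % d1, jy = (j / d1) % d2, jx = j / (d1 * d2);
    for (size_t k = 0; k < nb.size(); ++k) {
      int nz = jz + nb.dz[k], ny = jy + nb.dy[k], nx = jx + nb.dx[k];
      if (nz < 0 || nz >= d1 || ny < 0 || ny >= d2 || nx < 0 || nx >= d3) continue;
      int m = flat(nz, ny, nx, d1, d2);
      if (mask[m] && !out[m]) { out[m] = out[j]; q.push(m); }
    }
  }
  return out;
}
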