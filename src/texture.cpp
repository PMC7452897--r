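#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 13 unique 3D direction offsets (26-neighbourhood up to sign), distance 1.
static const int OFFS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int at(const IntegerVector &lab, int nx, int ny, int nz,
                     int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
  return lab[x + nx * (y + (R_xlen_t)ny * z)];
}

// Per-direction symmetric gray-level co-occurrence counts at distance 1.
// labels: 0 outside ROI, 1..n_bins inside. Returns n_bins x n_bins x 13.
// [[Rcpp::export(name = ".cpp_glcm_counts")]]
NumericVector cpp_glcm_counts(IntegerVector labels, IntegerVector dims,
                              int n_bins) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(Dimension(n_bins, n_bins, 13));
  for (int d = 0; d < 13; ++d) {
    const int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    double *slab = &out[(R_xlen_t)d * n_bins * n_bins];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = at(labels, nx, ny, nz, x, y, z);
          if (a == 0) continue;
          const int b = at(labels, nx, ny, nz, x + dx, y + dy, z + dz);
          if (b == 0) continue;
          slab[(a - 1) + n_bins * (b - 1)] += 1.0;  // forward
          slab[(b - 1) + n_bins * (a - 1)] += 1.0;  // symmetric
        }
  }
  return out;
}

// Per-direction gray-level run-length counts. A run is a maximal set of
// consecutive in-ROI voxels of equal gray level along the direction.
// Returns n_bins x max_run x 13 (max_run = longest grid diagonal bound).
// [[Rcpp::export(name = ".cpp_glrlm_counts")]]
NumericVector cpp_glrlm_counts(IntegerVector labels, IntegerVector dims,
                               int n_bins) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int max_run = std::max(nx, std::max(ny, nz));
  NumericVector out(Dimension(n_bins, max_run, 13));
  for (int d = 0; d < 13; ++d) {
    const int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    double *slab = &out[(R_xlen_t)d * n_bins * max_run];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          const int a = at(labels, nx, ny, nz, x, y, z);
          if (a == 0) continue;
          // run start: predecessor along -d is absent or different level
          if (at(labels, nx, ny, nz, x - dx, y - dy, z - dz) == a) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(labels, nx, ny, nz, cx, cy, cz) == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          slab[(a - 1) + n_bins * (len - 1)] += 1.0;
        }
  }
  return out;
}

// Gray-level size-zone counts: zones are 26-connected components of equal
// gray level. Returns n_bins x max_zone_size matrix of zone counts.
// [[Rcpp::export(name = ".cpp_glszm_counts")]]
NumericMatrix cpp_glszm_counts(IntegerVector labels, IntegerVector dims,
                               int n_bins) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (gray level, size)
  int max_size = 1;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (seen[s] || labels[s] == 0) continue;
    const int g = labels[s];
    int size = 0;
    std::queue<R_xlen_t> q;
    q.push(s);
    seen[s] = 1;
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      ++size;
      const int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int ax = x + dx, ay = y + dy, az = z + dz;
            if (ax < 0 || ay < 0 || az < 0 ||
                ax >= nx || ay >= ny || az >= nz) continue;
            const R_xlen_t w = ax + nx * (ay + (R_xlen_t)ny * az);
            if (!seen[w] && labels[w] == g) {
              seen[w] = 1;
              q.push(w);
            }
          }
    }
    zones.push_back(std::make_pair(g, size));
    if (size > max_size) max_size = size;
  }
  NumericMatrix out(n_bins, max_size);
  for (size_t i = 0; i < zones.size(); ++i)
    out(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return out;
}
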