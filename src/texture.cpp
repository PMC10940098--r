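#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// The 13 unique 3D direction offsets (distance-1 neighbors up to point symmetry).
static const int OFFS[13][3] = {
  {1, 0, 0},  {0, 1, 0},  {0, 0, 1},
  {1, 1, 0},  {1, -1, 0}, {1, 0, 1},  {1, 0, -1},
  {0, 1, 1},  {0, 1, -1},
  {1, 1, 1},  {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline R_xlen_t IDX(int x, int y, int z, int nx, int ny) {
  return x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
}

// Symmetric gray-level co-occurrence counts at distance 1 for each of the 13
// unique offsets. q: 0 outside the region, 1..G inside. Returns G x G x 13.
// [[Rcpp::export(name = ".glcm_counts")]]
NumericVector glcm_counts(IntegerVector q, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)G * G * 13);
  for (int t = 0; t < 13; ++t) {
    const int dx = OFFS[t][0], dy = OFFS[t][1], dz = OFFS[t][2];
    R_xlen_t base = (R_xlen_t)G * G * t;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = q[IDX(x, y, z, nx, ny)];
          if (a == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
            continue;
          int b = q[IDX(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          out[base + (a - 1) + (R_xlen_t)G * (b - 1)] += 1.0;
          out[base + (b - 1) + (R_xlen_t)G * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(G, G, 13);
  return out;
}

// Gray-level run-length counts summed over the 13 directions.
// Returns G x Lmax where Lmax = max(dim).
// [[Rcpp::export(name = ".glrlm_counts")]]
NumericMatrix glrlm_counts(IntegerVector q, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int lmax = std::max(nx, std::max(ny, nz));
  NumericMatrix out(G, lmax);
  for (int t = 0; t < 13; ++t) {
    const int dx = OFFS[t][0], dy = OFFS[t][1], dz = OFFS[t][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = q[IDX(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run start: predecessor along -offset is absent or different
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              q[IDX(xp, yp, zp, nx, ny)] == a)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz &&
                 q[IDX(xc, yc, zc, nx, ny)] == a) {
            ++len;
            xc += dx; yc += dy; zc += dz;
          }
          out(a - 1, len - 1) += 1.0;
        }
  }
  return out;
}

// Gray-level size-zone decomposition: 26-connected components of equal level.
// Returns a list with per-zone gray level and size.
// [[Rcpp::export(name = ".glszm_zones")]]
List glszm_zones(IntegerVector q, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> levels, sizes;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (q[i] == 0 || seen[i]) continue;
    const int lev = q[i];
    int size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      ++size;
      int cz = (int)(c / ((R_xlen_t)nx * ny));
      int rem = (int)(c - (R_xlen_t)nx * ny * cz);
      int cy = rem / nx, cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            R_xlen_t j = IDX(x2, y2, z2, nx, ny);
            if (!seen[j] && q[j] == lev) {
              seen[j] = 1;
              stack.push_back(j);
            }
          }
    }
    levels.push_back(lev);
    sizes.push_back(size);
  }
  return List::create(_["level"] = wrap(levels), _["size"] = wrap(sizes));
}

// Gray-level dependence counts: dependence size = 1 + number of in-region
// 26-neighbors sharing the center's level (alpha = 0). Returns G x 27.
// [[Rcpp::export(name = ".gldm_counts")]]
NumericMatrix gldm_counts(IntegerVector q, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(G, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = q[IDX(x, y, z, nx, ny)];
        if (a == 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              if (q[IDX(x2, y2, z2, nx, ny)] == a) ++dep;
            }
        out(a - 1, dep) += 1.0;
      }
  return out;
}

// Neighborhood gray-tone difference accumulators: for each level i, the count
// n_i of region voxels of level i with at least one in-region 26-neighbor, and
// s_i = sum over those voxels of |i - mean(neighbor levels)|.
// [[Rcpp::export(name = ".ngtdm_counts")]]
List ngtdm_counts(IntegerVector q, IntegerVector dim, int G) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector nvec(G), svec(G);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = q[IDX(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int b = q[IDX(x2, y2, z2, nx, ny)];
              if (b > 0) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          nvec[a - 1] += 1.0;
          svec[a - 1] += std::fabs((double)a - sum / cnt);
        }
      }
  return List::create(_["n"] = nvec, _["s"] = svec);
}

// Largest pairwise Euclidean distance between rows of a coordinate matrix (mm).
// [[Rcpp::export(name = ".max_pairwise_dist")]]
double max_pairwise_dist(NumericMatrix coords) {
  const int n = coords.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = coords(i, 0) - coords(j, 0);
      double dy = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
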