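#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 3D neighbourhood offsets for 6/18/26 connectivity.
static void neighbour_offsets(int connectivity,
                              std::vector<int> &dx,
                              std::vector<int> &dy,
                              std::vector<int> &dz) {
  int max_manhattan = (connectivity == 6) ? 1 : (connectivity == 18) ? 2 : 3;
  for (int k = -1; k <= 1; ++k)
    for (int j = -1; j <= 1; ++j)
      for (int i = -1; i <= 1; ++i) {
        int m = std::abs(i) + std::abs(j) + std::abs(k);
        if (m == 0 || m > max_manhattan) continue;
        dx.push_back(i); dy.push_back(j); dz.push_back(k);
      }
}

// Connected component of `mask` containing the (0-based) linear voxel `seed`.
// Returns an all-FALSE mask when the seed voxel itself is FALSE.
// [[Rcpp::export(name = ".cc_from_seed")]]
LogicalVector cc_from_seed(LogicalVector mask, IntegerVector dim,
                           int seed, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (seed < 0 || seed >= n) stop("seed voxel outside the grid");
  LogicalVector out(n, false);
  if (!mask[seed]) return out;

  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int noff = (int)dx.size();

  std::vector<int> stack;
  stack.push_back(seed);
  out[seed] = true;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
    for (int o = 0; o < noff; ++o) {
      int xx = x + dx[o], yy = y + dy[o], zz = z + dz[o];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
      int w = xx + nx * (yy + ny * zz);
      if (mask[w] && !out[w]) { out[w] = true; stack.push_back(w); }
    }
  }
  return out;
}

// Voxels outside `mask` whose Euclidean distance (mm, between voxel centres)
// to the nearest mask voxel lies in [inner, outer]. Distances to the mask are
// attained at its 6-connected surface voxels, so only those are scanned.
// [[Rcpp::export(name = ".shell_mask")]]
LogicalVector shell_mask(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing, double inner, double outer) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  // surface voxels + mask bounding box
  std::vector<int> su_x, su_y, su_z;
  int x0 = nx, x1 = -1, y0 = ny, y1 = -1, z0 = nz, z1 = -1;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (!mask[v]) continue;
        if (x < x0) x0 = x; if (x > x1) x1 = x;
        if (y < y0) y0 = y; if (y > y1) y1 = y;
        if (z < z0) z0 = z; if (z > z1) z1 = z;
        bool surf =
          (x == 0 || !mask[v - 1]) || (x == nx - 1 || !mask[v + 1]) ||
          (y == 0 || !mask[v - nx]) || (y == ny - 1 || !mask[v + nx]) ||
          (z == 0 || !mask[v - (R_xlen_t)nx * ny]) ||
          (z == nz - 1 || !mask[v + (R_xlen_t)nx * ny]);
        if (surf) { su_x.push_back(x); su_y.push_back(y); su_z.push_back(z); }
      }
  LogicalVector out(n, false);
  if (su_x.empty()) return out;

  const int mx = (int)std::ceil(outer / sx) + 1;
  const int my = (int)std::ceil(outer / sy) + 1;
  const int mz = (int)std::ceil(outer / sz) + 1;
  const int cx0 = std::max(0, x0 - mx), cx1 = std::min(nx - 1, x1 + mx);
  const int cy0 = std::max(0, y0 - my), cy1 = std::min(ny - 1, y1 + my);
  const int cz0 = std::max(0, z0 - mz), cz1 = std::min(nz - 1, z1 + mz);
  const double in2 = inner * inner, out2 = outer * outer;
  const size_t ns = su_x.size();

  for (int z = cz0; z <= cz1; ++z)
    for (int y = cy0; y <= cy1; ++y)
      for (int x = cx0; x <= cx1; ++x) {
        R_xlen_t v = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        if (mask[v]) continue;
        double best = R_PosInf;
        for (size_t s = 0; s < ns; ++s) {
          double ddx = (x - su_x[s]) * sx;
          double ddy = (y - su_y[s]) * sy;
          double ddz = (z - su_z[s]) * sz;
          double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
          if (d2 < best) {
            best = d2;
            if (best < in2) break;  // closer than the shell: excluded
          }
        }
        if (best >= in2 && best <= out2) out[v] = true;
      }
  return out;
}
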