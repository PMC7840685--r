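#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Triangle/axis-aligned-box overlap, separating axis test (Akenine-Moller).
// Box given by center and half-widths; triangle by its three vertices.
static inline bool axistest(double a, double b, double fa, double fb,
                            double v0p, double v0q, double v1p, double v1q,
                            double hp, double hq) {
  double p0 = a * v0p - b * v0q;
  double p1 = a * v1p - b * v1q;
  double mn = p0 < p1 ? p0 : p1, mx = p0 < p1 ? p1 : p0;
  double rad = fa * hp + fb * hq;
  return !(mn > rad || mx < -rad);
}

static bool tri_box_overlap(const double c[3], const double h[3],
                            const double t0[3], const double t1[3], const double t2[3]) {
  double v0[3], v1[3], v2[3];
  for (int i = 0; i < 3; ++i) {
    v0[i] = t0[i] - c[i];
    v1[i] = t1[i] - c[i];
    v2[i] = t2[i] - c[i];
  }
  double e0[3], e1[3], e2[3];
  for (int i = 0; i < 3; ++i) {
    e0[i] = v1[i] - v0[i];
    e1[i] = v2[i] - v1[i];
    e2[i] = v0[i] - v2[i];
  }
  double fex, fey, fez;
  // 9 cross-product axes
  fex = std::fabs(e0[0]); fey = std::fabs(e0[1]); fez = std::fabs(e0[2]);
  if (!axistest(e0[2], e0[1], fez, fey, v0[1], v0[2], v2[1], v2[2], h[1], h[2])) return false;
  if (!axistest(e0[2], e0[0], fez, fex, v0[0], v0[2], v2[0], v2[2], h[0], h[2])) return false;
  if (!axistest(e0[1], e0[0], fey, fex, v1[0], v1[1], v2[0], v2[1], h[0], h[1])) return false;
  fex = std::fabs(e1[0]); fey = std::fabs(e1[1]); fez = std::fabs(e1[2]);
  if (!axistest(e1[2], e1[1], fez, fey, v0[1], v0[2], v2[1], v2[2], h[1], h[2])) return false;
  if (!axistest(e1[2], e1[0], fez, fex, v0[0], v0[2], v2[0], v2[2], h[0], h[2])) return false;
  if (!axistest(e1[1], e1[0], fey, fex, v0[0], v0[1], v1[0], v1[1], h[0], h[1])) return false;
  fex = std::fabs(e2[0]); fey = std::fabs(e2[1]); fez = std::fabs(e2[2]);
  if (!axistest(e2[2], e2[1], fez, fey, v0[1], v0[2], v1[1], v1[2], h[1], h[2])) return false;
  if (!axistest(e2[2], e2[0], fez, fex, v0[0], v0[2], v1[0], v1[2], h[0], h[2])) return false;
  if (!axistest(e2[1], e2[0], fey, fex, v1[0], v1[1], v2[0], v2[1], h[0], h[1])) return false;
  // box face normals
  for (int i = 0; i < 3; ++i) {
    double mn = std::min(v0[i], std::min(v1[i], v2[i]));
    double mx = std::max(v0[i], std::max(v1[i], v2[i]));
    if (mn > h[i] || mx < -h[i]) return false;
  }
  // triangle plane
  double n[3] = {e0[1] * e1[2] - e0[2] * e1[1],
                 e0[2] * e1[0] - e0[0] * e1[2],
                 e0[0] * e1[1] - e0[1] * e1[0]};
  double d = -(n[0] * v0[0] + n[1] * v0[1] + n[2] * v0[2]);
  double vmin[3], vmax[3];
  for (int i = 0; i < 3; ++i) {
    if (n[i] > 0) { vmin[i] = -h[i]; vmax[i] = h[i]; }
    else          { vmin[i] =  h[i]; vmax[i] = -h[i]; }
  }
  if (n[0] * vmin[0] + n[1] * vmin[1] + n[2] * vmin[2] + d > 0) return false;
  if (n[0] * vmax[0] + n[1] * vmax[1] + n[2] * vmax[2] + d < 0) return false;
  return true;
}

// Exact surface voxelization: a voxel is occupied iff some face intersects its cube.
// V: vertices (um), F: 0-based triangle indices, origin: grid min corner (um),
// side: voxel edge (um), dims: grid extents in voxels.
// [[Rcpp::export]]
IntegerMatrix voxelize_mesh_cpp(NumericMatrix V, IntegerMatrix F,
                                NumericVector origin, double side,
                                IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::unordered_set<long long> occ;
  occ.reserve(1024);
  const double h[3] = {side / 2.0, side / 2.0, side / 2.0};
  for (int f = 0; f < F.nrow(); ++f) {
    double t0[3], t1[3], t2[3];
    for (int i = 0; i < 3; ++i) {
      t0[i] = V(F(f, 0), i) - origin[i];
      t1[i] = V(F(f, 1), i) - origin[i];
      t2[i] = V(F(f, 2), i) - origin[i];
    }
    int lo[3], hi[3];
    for (int i = 0; i < 3; ++i) {
      double mn = std::min(t0[i], std::min(t1[i], t2[i]));
      double mx = std::max(t0[i], std::max(t1[i], t2[i]));
      lo[i] = std::max(0, (int)std::floor(mn / side - 1e-12));
      hi[i] = std::min((i == 0 ? nx : (i == 1 ? ny : nz)) - 1,
                       (int)std::floor(mx / side + 1e-12));
    }
    for (int x = lo[0]; x <= hi[0]; ++x)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int z = lo[2]; z <= hi[2]; ++z) {
          long long key = (long long)x + (long long)nx * ((long long)y + (long long)ny * z);
          if (occ.count(key)) continue;
          double c[3] = {(x + 0.5) * side, (y + 0.5) * side, (z + 0.5) * side};
          if (tri_box_overlap(c, h, t0, t1, t2)) occ.insert(key);
        }
  }
  IntegerMatrix out(occ.size(), 3);
  int r = 0;
  for (long long key : occ) {
    out(r, 0) = (int)(key % nx);
    out(r, 1) = (int)((key / nx) % ny);
    out(r, 2) = (int)(key / ((long long)nx * ny));
    ++r;
  }
  return out;
}

// Interior voxels of a (sub)grid by 6-connected flood fill from the outside.
// Operates on the slab x in [x0, x1]; seeds are empty cells lying on the global
// grid boundary (y/z faces always; x faces only where the slab touches the
// global ends). Returns coordinates of unreached (interior) cells with
// x in [core0, core1].
// [[Rcpp::export]]
IntegerMatrix flood_interior_cpp(IntegerMatrix coords, IntegerVector dims,
                                 int x0, int x1, int core0, int core1) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sx = x1 - x0 + 1;
  const size_t ncell = (size_t)sx * ny * nz;
  std::vector<unsigned char> st(ncell, 0); // 0 empty, 1 surface, 2 exterior
  auto idx = [&](int x, int y, int z) {
    return (size_t)(x - x0) + (size_t)sx * ((size_t)y + (size_t)ny * z);
  };
  for (int i = 0; i < coords.nrow(); ++i) {
    int x = coords(i, 0);
    if (x < x0 || x > x1) continue;
    st[idx(x, coords(i, 1), coords(i, 2))] = 1;
  }
  std::vector<size_t> queue;
  queue.reserve(1 << 16);
  auto seed = [&](int x, int y, int z) {
    size_t k = idx(x, y, z);
    if (st[k] == 0) { st[k] = 2; queue.push_back(k); }
  };
  for (int x = x0; x <= x1; ++x)
    for (int y = 0; y < ny; ++y) {
      seed(x, y, 0);
      seed(x, y, nz - 1);
    }
  for (int x = x0; x <= x1; ++x)
    for (int z = 0; z < nz; ++z) {
      seed(x, 0, z);
      seed(x, ny - 1, z);
    }
  if (x0 == 0)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) seed(0, y, z);
  if (x1 == nx - 1)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) seed(nx - 1, y, z);
  while (!queue.empty()) {
    size_t k = queue.back();
    queue.pop_back();
    int x = x0 + (int)(k % sx);
    int y = (int)((k / sx) % ny);
    int z = (int)(k / ((size_t)sx * ny));
    if (x > x0) seed(x - 1, y, z);
    if (x < x1) seed(x + 1, y, z);
    if (y > 0) seed(x, y - 1, z);
    if (y < ny - 1) seed(x, y + 1, z);
    if (z > 0) seed(x, y, z - 1);
    if (z < nz - 1) seed(x, y, z + 1);
  }
  std::vector<int> xs, ys, zs;
  for (int x = std::max(core0, x0); x <= std::min(core1, x1); ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z)
        if (st[idx(x, y, z)] == 0) {
          xs.push_back(x);
          ys.push_back(y);
          zs.push_back(z);
        }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
    out(i, 2) = zs[i];
  }
  return out;
}
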