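#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Orthographic projection areas of a point cloud for a set of view directions.
// Each direction is mapped onto the -z axis by the minimal rotation; points are
// rotated, their (x, y) coordinates rounded to a lattice of spacing `cell`
// anchored at the rotated centroid, and the number of distinct lattice cells is
// returned per direction (duplicates along the view axis are blocking).
// [[Rcpp::export]]
NumericVector project_count_cpp(NumericMatrix P, NumericMatrix dirs, double cell) {
  const int n = P.nrow(), nd = dirs.nrow();
  NumericVector out(nd);
  // conservative bound on lattice extents for the dense marking plane
  double rmax = 0.0;
  std::vector<double> px(n), py(n), pz(n);
  double mx = 0, my = 0, mz = 0;
  for (int i = 0; i < n; ++i) {
    px[i] = P(i, 0); py[i] = P(i, 1); pz[i] = P(i, 2);
    mx += px[i]; my += py[i]; mz += pz[i];
  }
  mx /= n; my /= n; mz /= n;
  for (int i = 0; i < n; ++i) {
    double d2 = (px[i] - mx) * (px[i] - mx) + (py[i] - my) * (py[i] - my) +
                (pz[i] - mz) * (pz[i] - mz);
    if (d2 > rmax) rmax = d2;
  }
  const int half = (int)std::ceil(std::sqrt(rmax) / cell) + 3;
  const int w = 2 * half + 1;
  std::vector<unsigned int> mark((size_t)w * w, 0u);
  unsigned int epoch = 0;
  std::vector<double> u(n), v(n);
  for (int d = 0; d < nd; ++d) {
    double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    double nrm = std::sqrt(dx * dx + dy * dy + dz * dz);
    dx /= nrm; dy /= nrm; dz /= nrm;
    // rotation taking (dx,dy,dz) to (0,0,-1): axis = d x t, t = (0,0,-1)
    double R[3][3];
    double c = -dz; // cos(theta) = d . t
    if (c > 1.0 - 1e-12) {
      R[0][0] = 1; R[0][1] = 0; R[0][2] = 0;
      R[1][0] = 0; R[1][1] = 1; R[1][2] = 0;
      R[2][0] = 0; R[2][1] = 0; R[2][2] = 1;
    } else if (c < -1.0 + 1e-12) {
      // antipode: 180 degrees about x
      R[0][0] = 1; R[0][1] = 0; R[0][2] = 0;
      R[1][0] = 0; R[1][1] = -1; R[1][2] = 0;
      R[2][0] = 0; R[2][1] = 0; R[2][2] = -1;
    } else {
      double ax = -dy, ay = dx, az = 0.0; // d x (0,0,-1) = (-dy, dx, 0)
      double s = std::sqrt(ax * ax + ay * ay);
      ax /= s; ay /= s;
      double st = s, ct = c, omc = 1.0 - c;
      R[0][0] = ct + ax * ax * omc; R[0][1] = ax * ay * omc - az * st; R[0][2] = ax * az * omc + ay * st;
      R[1][0] = ay * ax * omc + az * st; R[1][1] = ct + ay * ay * omc; R[1][2] = ay * az * omc - ax * st;
      R[2][0] = az * ax * omc - ay * st; R[2][1] = az * ay * omc + ax * st; R[2][2] = ct + az * az * omc;
    }
    double cu = 0, cv = 0;
    for (int i = 0; i < n; ++i) {
      u[i] = R[0][0] * px[i] + R[0][1] * py[i] + R[0][2] * pz[i];
      v[i] = R[1][0] * px[i] + R[1][1] * py[i] + R[1][2] * pz[i];
      cu += u[i]; cv += v[i];
    }
    cu /= n; cv /= n;
    ++epoch;
    if (epoch == 0u) { std::fill(mark.begin(), mark.end(), 0u); epoch = 1; }
    long long cnt = 0;
    for (int i = 0; i < n; ++i) {
      int iu = (int)std::lround((u[i] - cu) / cell) + half;
      int iv = (int)std::lround((v[i] - cv) / cell) + half;
      size_t k = (size_t)iu * w + iv;
      if (mark[k] != epoch) { mark[k] = epoch; ++cnt; }
    }
    out[d] = (double)cnt;
  }
  return out;
}

// Strict point-in-cylinder test against a set of segments, skipping a forbidden
// segment id per point (a face's own segment). Segments are finite cylinders;
// a point is inside iff its axial coordinate lies strictly in (0, len) and its
// radial distance is strictly below the segment radius. Uniform-grid pruning.
// [[Rcpp::export]]
LogicalVector points_in_segments_cpp(NumericMatrix P, IntegerVector forbid,
                                     NumericMatrix S) {
  const int n = P.nrow(), m = S.nrow();
  LogicalVector out(n);
  if (m == 0) return out;
  double rmax = 0, lsum = 0;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int j = 0; j < m; ++j) {
    rmax = std::max(rmax, S(j, 6));
    double dx = S(j, 3) - S(j, 0), dy = S(j, 4) - S(j, 1), dz = S(j, 5) - S(j, 2);
    lsum += std::sqrt(dx * dx + dy * dy + dz * dz);
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], std::min(S(j, a), S(j, a + 3)));
      hi[a] = std::max(hi[a], std::max(S(j, a), S(j, a + 3)));
    }
  }
  double h = std::max(2.0 * rmax, lsum / m);
  if (h <= 0) h = 1.0;
  int nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
  int ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
  int nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
  std::vector<std::vector<int> > cells((size_t)nx * ny * nz);
  auto cidx = [&](int x, int y, int z) {
    return (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
  };
  auto clampi = [](int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); };
  for (int j = 0; j < m; ++j) {
    double r = S(j, 6);
    int c0[3], c1[3];
    for (int a = 0; a < 3; ++a) {
      double mn = std::min(S(j, a), S(j, a + 3)) - r;
      double mxv = std::max(S(j, a), S(j, a + 3)) + r;
      c0[a] = clampi((int)std::floor((mn - lo[a]) / h), a == 0 ? nx : (a == 1 ? ny : nz));
      c1[a] = clampi((int)std::floor((mxv - lo[a]) / h), a == 0 ? nx : (a == 1 ? ny : nz));
    }
    for (int x = c0[0]; x <= c1[0]; ++x)
      for (int y = c0[1]; y <= c1[1]; ++y)
        for (int z = c0[2]; z <= c1[2]; ++z)
          cells[cidx(x, y, z)].push_back(j);
  }
  for (int i = 0; i < n; ++i) {
    double p0 = P(i, 0), p1 = P(i, 1), p2 = P(i, 2);
    int cx = clampi((int)std::floor((p0 - lo[0]) / h), nx);
    int cy = clampi((int)std::floor((p1 - lo[1]) / h), ny);
    int cz = clampi((int)std::floor((p2 - lo[2]) / h), nz);
    bool inside = false;
    const std::vector<int>& cand = cells[cidx(cx, cy, cz)];
    for (size_t q = 0; q < cand.size() && !inside; ++q) {
      int j = cand[q];
      if (j + 1 == forbid[i]) continue;
      double ax = S(j, 0), ay = S(j, 1), az = S(j, 2);
      double dx = S(j, 3) - ax, dy = S(j, 4) - ay, dz = S(j, 5) - az;
      double len2 = dx * dx + dy * dy + dz * dz;
      if (len2 <= 0) continue;
      double wx = p0 - ax, wy = p1 - ay, wz = p2 - az;
      double t = (wx * dx + wy * dy + wz * dz) / len2;
      if (t <= 0.0 || t >= 1.0) continue;
      double qx = wx - t * dx, qy = wy - t * dy, qz = wz - t * dz;
      double rad2 = qx * qx + qy * qy + qz * qz;
      if (rad2 < S(j, 6) * S(j, 6) * (1.0 - 1e-12)) inside = true;
    }
    out[i] = inside;
  }
  return out;
}
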