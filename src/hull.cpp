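#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <utility>
using namespace Rcpp;

// Incremental (quickhull-style) 3D convex hull with conflict lists.
// Returns total facet area and enclosed volume; degenerate (coplanar) inputs
// are reported with a flag so the caller can fall back to a planar hull.

namespace {

struct Face {
  int v[3];
  int nb[3];     // neighbor across edge (v[i], v[(i+1)%3])
  double n[3];   // outward normal (not normalized)
  double off;    // n . x = off on the plane
  std::vector<int> pts; // conflict points
  bool alive;
};

inline void sub(const double* a, const double* b, double* o) {
  o[0] = a[0] - b[0]; o[1] = a[1] - b[1]; o[2] = a[2] - b[2];
}
inline void cross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

class Hull {
public:
  const NumericMatrix& P;
  std::vector<Face> faces;
  double eps;
  bool degenerate;

  Hull(const NumericMatrix& P_) : P(P_), degenerate(false) {}

  void pt(int i, double* o) const { o[0] = P(i, 0); o[1] = P(i, 1); o[2] = P(i, 2); }

  double dist(int f, int i) const {
    double p[3];
    pt(i, p);
    return dot(faces[f].n, p) - faces[f].off;
  }

  void setPlane(Face& f) {
    double a[3], b[3], c[3], e1[3], e2[3];
    pt(f.v[0], a); pt(f.v[1], b); pt(f.v[2], c);
    sub(b, a, e1); sub(c, a, e2);
    cross(e1, e2, f.n);
    f.off = dot(f.n, a);
  }

  bool init() {
    const int n = P.nrow();
    if (n < 4) { degenerate = true; return false; }
    // bounding scale
    double lo[3] = {R_PosInf, R_PosInf, R_PosInf}, hi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int i = 0; i < n; ++i)
      for (int a = 0; a < 3; ++a) {
        lo[a] = std::min(lo[a], P(i, a));
        hi[a] = std::max(hi[a], P(i, a));
      }
    double scale = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
    if (scale <= 0) { degenerate = true; return false; }
    eps = 1e-10 * scale;
    // farthest pair among axis extremes
    int ext[6];
    for (int a = 0; a < 3; ++a) {
      int imin = 0, imax = 0;
      for (int i = 1; i < n; ++i) {
        if (P(i, a) < P(imin, a)) imin = i;
        if (P(i, a) > P(imax, a)) imax = i;
      }
      ext[2 * a] = imin; ext[2 * a + 1] = imax;
    }
    int i0 = 0, i1 = 1;
    double best = -1;
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        double pa[3], pb[3], d[3];
        pt(ext[a], pa); pt(ext[b], pb); sub(pa, pb, d);
        double dd = dot(d, d);
        if (dd > best) { best = dd; i0 = ext[a]; i1 = ext[b]; }
      }
    if (best <= eps * eps) { degenerate = true; return false; }
    // farthest from the line i0-i1
    double p0[3], p1[3], dl[3];
    pt(i0, p0); pt(i1, p1); sub(p1, p0, dl);
    double ll = dot(dl, dl);
    int i2 = -1; best = -1;
    for (int i = 0; i < n; ++i) {
      double w[3], c[3], pi[3];
      pt(i, pi); sub(pi, p0, w); cross(dl, w, c);
      double d2 = dot(c, c) / ll;
      if (d2 > best) { best = d2; i2 = i; }
    }
    if (best <= eps * eps) { degenerate = true; return false; }
    // farthest from the plane i0,i1,i2
    double p2[3], e2[3], nrm[3];
    pt(i2, p2); sub(p2, p0, e2); cross(dl, e2, nrm);
    double nn = std::sqrt(dot(nrm, nrm));
    int i3 = -1; best = -1;
    for (int i = 0; i < n; ++i) {
      double pi[3], w[3];
      pt(i, pi); sub(pi, p0, w);
      double d = std::fabs(dot(nrm, w)) / nn;
      if (d > best) { best = d; i3 = i; }
    }
    if (best <= eps) { degenerate = true; return false; }
    // build tetrahedron with outward orientation
    double p3[3], w[3];
    pt(i3, p3); sub(p3, p0, w);
    bool above = dot(nrm, w) > 0;
    int t[4] = {i0, i1, i2, i3};
    int fv[4][3];
    if (above) {
      int tmp[4][3] = {{0, 2, 1}, {0, 1, 3}, {1, 2, 3}, {2, 0, 3}};
      for (int f = 0; f < 4; ++f) for (int k = 0; k < 3; ++k) fv[f][k] = t[tmp[f][k]];
    } else {
      int tmp[4][3] = {{0, 1, 2}, {0, 3, 1}, {1, 3, 2}, {2, 3, 0}};
      for (int f = 0; f < 4; ++f) for (int k = 0; k < 3; ++k) fv[f][k] = t[tmp[f][k]];
    }
    faces.resize(4);
    std::map<std::pair<int, int>, std::pair<int, int> > emap;
    for (int f = 0; f < 4; ++f) {
      Face& F = faces[f];
      F.v[0] = fv[f][0]; F.v[1] = fv[f][1]; F.v[2] = fv[f][2];
      F.alive = true;
      setPlane(F);
      for (int k = 0; k < 3; ++k) F.nb[k] = -1;
    }
    linkAll();
    // conflict lists
    for (int i = 0; i < n; ++i) {
      if (i == i0 || i == i1 || i == i2 || i == i3) continue;
      assignPoint(i);
    }
    return true;
  }

  void linkAll() {
    std::map<std::pair<int, int>, std::pair<int, int> > emap;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      for (int k = 0; k < 3; ++k) {
        int a = faces[f].v[k], b = faces[f].v[(k + 1) % 3];
        std::pair<int, int> key(std::min(a, b), std::max(a, b));
        std::map<std::pair<int, int>, std::pair<int, int> >::iterator it = emap.find(key);
        if (it == emap.end()) emap[key] = std::make_pair((int)f, k);
        else {
          faces[f].nb[k] = it->second.first;
          faces[it->second.first].nb[it->second.second] = (int)f;
        }
      }
    }
  }

  void assignPoint(int i) {
    int bestf = -1;
    double bestd = eps;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double d = dist((int)f, i);
      if (d > bestd) { bestd = d; bestf = (int)f; }
    }
    if (bestf >= 0) faces[bestf].pts.push_back(i);
  }

  void run() {
    bool progress = true;
    while (progress) {
      progress = false;
      for (size_t f = 0; f < faces.size(); ++f) {
        if (!faces[f].alive || faces[f].pts.empty()) continue;
        // farthest conflict point of this face
        int p = -1;
        double bestd = -1;
        for (size_t q = 0; q < faces[f].pts.size(); ++q) {
          double d = dist((int)f, faces[f].pts[q]);
          if (d > bestd) { bestd = d; p = faces[f].pts[q]; }
        }
        if (bestd <= eps) { faces[f].pts.clear(); continue; }
        addPoint(p, (int)f);
        progress = true;
        break;
      }
    }
  }

  void addPoint(int p, int f0) {
    // find visible faces by BFS
    std::vector<int> visible;
    std::vector<int> stack;
    std::vector<char> seen(faces.size(), 0);
    stack.push_back(f0);
    seen[f0] = 1;
    while (!stack.empty()) {
      int f = stack.back();
      stack.pop_back();
      visible.push_back(f);
      for (int k = 0; k < 3; ++k) {
        int g = faces[f].nb[k];
        if (g >= 0 && !seen[g] && faces[g].alive && dist(g, p) > eps) {
          seen[g] = 1;
          stack.push_back(g);
        }
      }
    }
    // horizon edges: edges of visible faces whose neighbor is not visible
    std::vector<int> horizF, horizK;
    for (size_t q = 0; q < visible.size(); ++q) {
      int f = visible[q];
      for (int k = 0; k < 3; ++k) {
        int g = faces[f].nb[k];
        if (g < 0 || !seen[g]) { horizF.push_back(f); horizK.push_back(k); }
      }
    }
    // collect conflict points of visible faces, kill them
    std::vector<int> orphans;
    for (size_t q = 0; q < visible.size(); ++q) {
      int f = visible[q];
      for (size_t r = 0; r < faces[f].pts.size(); ++r)
        if (faces[f].pts[r] != p) orphans.push_back(faces[f].pts[r]);
      faces[f].pts.clear();
      faces[f].alive = false;
    }
    // build new faces over horizon edges
    std::map<int, int> firstEdge; // from-vertex -> new face index (for linking ring)
    std::vector<int> newIdx;
    std::map<std::pair<int, int>, std::pair<int, int> > emap;
    for (size_t q = 0; q < horizF.size(); ++q) {
      int f = horizF[q], k = horizK[q];
      int a = faces[f].v[k], b = faces[f].v[(k + 1) % 3];
      Face nf;
      nf.v[0] = a; nf.v[1] = b; nf.v[2] = p;
      nf.alive = true;
      setPlane(nf);
      nf.nb[0] = faces[f].nb[k]; // across (a,b): the non-visible neighbor
      nf.nb[1] = -1; nf.nb[2] = -1;
      faces.push_back(nf);
      int idx = (int)faces.size() - 1;
      newIdx.push_back(idx);
      // fix the neighbor's back-pointer
      int g = faces[f].nb[k];
      if (g >= 0) {
        for (int kk = 0; kk < 3; ++kk) {
          int ga = faces[g].v[kk], gb = faces[g].v[(kk + 1) % 3];
          if ((ga == a && gb == b) || (ga == b && gb == a)) faces[g].nb[kk] = idx;
        }
      }
      // ring edges (b, p) and (p, a)
      std::pair<int, int> e1(std::min(b, p), std::max(b, p));
      std::pair<int, int> e2(std::min(p, a), std::max(p, a));
      if (emap.count(e1)) {
        faces[idx].nb[1] = emap[e1].first;
        faces[emap[e1].first].nb[emap[e1].second] = idx;
      } else emap[e1] = std::make_pair(idx, 1);
      if (emap.count(e2)) {
        faces[idx].nb[2] = emap[e2].first;
        faces[emap[e2].first].nb[emap[e2].second] = idx;
      } else emap[e2] = std::make_pair(idx, 2);
    }
    // reassign orphans to the new faces
    for (size_t q = 0; q < orphans.size(); ++q) {
      int i = orphans[q];
      int bestf = -1;
      double bestd = eps;
      for (size_t r = 0; r < newIdx.size(); ++r) {
        double d = dist(newIdx[r], i);
        if (d > bestd) { bestd = d; bestf = newIdx[r]; }
      }
      if (bestf >= 0) faces[bestf].pts.push_back(i);
    }
  }
};

} // namespace

// [[Rcpp::export]]
List convex_hull_cpp(NumericMatrix P) {
  Hull H(P);
  if (!H.init()) {
    return List::create(Named("area") = NA_REAL, Named("volume") = 0.0,
                        Named("degenerate") = true,
                        Named("vertices") = IntegerVector(0));
  }
  H.run();
  double area = 0.0, volume = 0.0;
  // reference point for volume: mean of hull face vertices
  double ref[3] = {0, 0, 0};
  int nv = 0;
  std::vector<char> used(P.nrow(), 0);
  for (size_t f = 0; f < H.faces.size(); ++f) {
    if (!H.faces[f].alive) continue;
    for (int k = 0; k < 3; ++k)
      if (!used[H.faces[f].v[k]]) {
        used[H.faces[f].v[k]] = 1;
        for (int a = 0; a < 3; ++a) ref[a] += P(H.faces[f].v[k], a);
        ++nv;
      }
  }
  for (int a = 0; a < 3; ++a) ref[a] /= nv;
  std::vector<int> hv;
  for (int i = 0; i < P.nrow(); ++i)
    if (used[i]) hv.push_back(i + 1);
  for (size_t f = 0; f < H.faces.size(); ++f) {
    if (!H.faces[f].alive) continue;
    double a[3], b[3], c[3];
    H.pt(H.faces[f].v[0], a);
    H.pt(H.faces[f].v[1], b);
    H.pt(H.faces[f].v[2], c);
    double e1[3], e2[3], cr[3];
    sub(b, a, e1); sub(c, a, e2); cross(e1, e2, cr);
    area += 0.5 * std::sqrt(dot(cr, cr));
    double w[3];
    sub(a, ref, w);
    volume += dot(cr, w) / 6.0;
  }
  return List::create(Named("area") = area, Named("volume") = std::fabs(volume),
                      Named("degenerate") = false,
                      Named("vertices") = wrap(hv));
}
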