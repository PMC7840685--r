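#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Sliding box count. Boxes of (possibly fractional, in voxel units) size b tile
// the grid from the origin; the partition is slid diagonally (all three axes
// together) by multiples of step_vox and the minimum occupied-box count over
// offsets is kept. A box counts as occupied if any occupied voxel's (half-open)
// cube intersects it, so a voxel can contribute to up to 8 boxes when the box
// edges are not voxel-aligned.
// [[Rcpp::export]]
IntegerVector box_count_cpp(IntegerMatrix coords, IntegerVector dims,
                            NumericVector box_sizes_vox, double step_vox,
                            int max_offsets) {
  const int n = coords.nrow();
  const int nsz = box_sizes_vox.size();
  IntegerVector out(nsz);
  std::vector<unsigned int> mark;
  unsigned int epoch = 0; // global epoch: the mark array is reused across sizes
  for (int s = 0; s < nsz; ++s) {
    const double b = box_sizes_vox[s];
    int noff = (int)std::ceil(b / step_vox - 1e-9);
    if (noff < 1) noff = 1;
    if (noff > max_offsets) noff = max_offsets;
    // box index range: with shift delta in [0, b), index floor((i + delta)/b)
    const int nbx = (int)std::floor((dims[0] + b) / b) + 2;
    const int nby = (int)std::floor((dims[1] + b) / b) + 2;
    const int nbz = (int)std::floor((dims[2] + b) / b) + 2;
    const size_t nbox = (size_t)nbx * nby * nbz;
    const bool dense = nbox <= (size_t)5e7; // hash fallback for huge sparse grids
    if (dense && mark.size() < nbox) mark.resize(nbox, 0u);
    std::unordered_set<long long> hset;
    int best = -1;
    for (int o = 0; o < noff; ++o) {
      const double delta = o * step_vox;
      ++epoch;
      if (epoch == 0u) { std::fill(mark.begin(), mark.end(), 0u); epoch = 1; }
      if (!dense) { hset.clear(); hset.reserve(2 * n); }
      int cnt = 0;
      for (int i = 0; i < n; ++i) {
        const double x = coords(i, 0) + delta;
        const double y = coords(i, 1) + delta;
        const double z = coords(i, 2) + delta;
        const int mx0 = (int)std::floor(x / b), mx1 = (int)std::floor((x + 1.0 - 1e-9) / b);
        const int my0 = (int)std::floor(y / b), my1 = (int)std::floor((y + 1.0 - 1e-9) / b);
        const int mz0 = (int)std::floor(z / b), mz1 = (int)std::floor((z + 1.0 - 1e-9) / b);
        for (int mx = mx0; mx <= mx1; ++mx)
          for (int my = my0; my <= my1; ++my)
            for (int mz = mz0; mz <= mz1; ++mz) {
              long long k = (long long)mx + (long long)nbx * ((long long)my + (long long)nby * mz);
              if (dense) {
                if (mark[(size_t)k] != epoch) { mark[(size_t)k] = epoch; ++cnt; }
              } else {
                if (hset.insert(k).second) ++cnt;
              }
            }
      }
      if (best < 0 || cnt < best) best = cnt;
      if (best == 1) break; // cannot do better
    }
    out[s] = best;
  }
  return out;
}
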