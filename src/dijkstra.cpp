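#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-source Dijkstra over the 26-connected voxel lattice.
//
// Edge weight between neighboring voxels i, j:
//   w_ij = ||p_i - p_j|| + 2c / (I'_i + I'_j),  I'_k = min(max(I_k, 1), I_max)
// with positions in world um (anisotropic spacing). The lower clamp at 1
// keeps weights finite for zero-intensity voxels.
//
// The search may be restricted to an axis-aligned sub-box (1-based inclusive
// bounds); voxels outside keep cost Inf and predecessor NA.
//
// Ties in tentative cost are broken toward the smaller linear voxel index so
// that traced paths are deterministic.

// [[Rcpp::export]]
List dijkstra_tree_cpp(NumericVector img, IntegerVector dims,
                       NumericVector spacing, int root,
                       double c, double imax,
                       IntegerVector sub_lo, IntegerVector sub_hi) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  const int lx = sub_lo[0] - 1, ly = sub_lo[1] - 1, lz = sub_lo[2] - 1;
  const int hx = sub_hi[0] - 1, hy = sub_hi[1] - 1, hz = sub_hi[2] - 1;

  std::vector<double> dist(nvox, R_PosInf);
  std::vector<int> pred(nvox, -1);        // -1: unset
  std::vector<char> done(nvox, 0);

  // precompute clamped intensities
  std::vector<double> ic(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) {
    double v = img[i];
    if (v < 1.0) v = 1.0;
    if (v > imax) v = imax;
    ic[i] = v;
  }

  // neighbor offsets and step lengths (26-neighborhood)
  int noff[26][3]; double nlen[26]; int nn = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        noff[nn][0] = dx; noff[nn][1] = dy; noff[nn][2] = dz;
        nlen[nn] = std::sqrt(dx * dx * sx * sx + dy * dy * sy * sy +
                             dz * dz * sz * sz);
        ++nn;
      }

  typedef std::pair<double, R_xlen_t> QE;  // (cost, index); min-heap
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  const R_xlen_t r0 = (R_xlen_t)(root - 1);
  dist[r0] = 0.0;
  pred[r0] = 0;                            // root marks itself with 0
  pq.push(QE(0.0, r0));

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (done[u]) continue;
    done[u] = 1;
    const int ux = (int)(u % nx);
    const int uy = (int)((u / nx) % ny);
    const int uz = (int)(u / ((R_xlen_t)nx * ny));
    for (int k = 0; k < 26; ++k) {
      const int vx = ux + noff[k][0];
      const int vy = uy + noff[k][1];
      const int vz = uz + noff[k][2];
      if (vx < lx || vx > hx || vy < ly || vy > hy || vz < lz || vz > hz)
        continue;
      const R_xlen_t v = vx + (R_xlen_t)nx * vy + (R_xlen_t)nx * ny * vz;
      if (done[v]) continue;
      const double w = nlen[k] + 2.0 * c / (ic[u] + ic[v]);
      const double nd = top.first + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = (int)(u + 1);            // 1-based linear index
        pq.push(QE(nd, v));
      } else if (nd == dist[v] && pred[v] > (int)(u + 1)) {
        pred[v] = (int)(u + 1);            // deterministic tie-break
      }
    }
  }

  IntegerVector predR(nvox);
  NumericVector costR(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) {
    predR[i] = (pred[i] < 0) ? NA_INTEGER : pred[i];
    costR[i] = dist[i];
  }
  return List::create(_["pred"] = predR, _["cost"] = costR);
}
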