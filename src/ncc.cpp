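#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pearson-style normalized cross correlation of two equal-length patches.
// Returns NA if either patch has zero variance.
// [[Rcpp::export]]
double ncc_cpp(NumericVector a, NumericVector b) {
  const R_xlen_t n = a.size();
  double ma = 0, mb = 0;
  for (R_xlen_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return NA_REAL;
  return sab / std::sqrt(saa * sbb);
}

// Exhaustive NCC template matching.
//
// The template is the box of size tsize centered (floor-half convention) at
// `center` (1-based voxel xyz) in img_prev. Every integer displacement d in
// the search window of size ssize is evaluated; the NCC is computed over the
// voxels where both the template box in img_prev and its displaced copy in
// img_cur are inside their lattices (boxes clipped at borders).
//
// Ties in score are broken by smaller squared voxel displacement, then by
// lexicographically smaller (dx, dy, dz).
// [[Rcpp::export]]
List match_template_cpp(NumericVector img_prev, IntegerVector dims_prev,
                        NumericVector img_cur, IntegerVector dims_cur,
                        IntegerVector center, IntegerVector tsize,
                        IntegerVector ssize) {
  const int pnx = dims_prev[0], pny = dims_prev[1], pnz = dims_prev[2];
  const int cnx = dims_cur[0], cny = dims_cur[1], cnz = dims_cur[2];
  const int cx = center[0] - 1, cy = center[1] - 1, cz = center[2] - 1;

  int tlo[3], thi[3], slo[3], shi[3];
  for (int ax = 0; ax < 3; ++ax) {
    tlo[ax] = -(tsize[ax] / 2); thi[ax] = tsize[ax] - 1 - tsize[ax] / 2;
    slo[ax] = -(ssize[ax] / 2); shi[ax] = ssize[ax] - 1 - ssize[ax] / 2;
  }

  double best = NA_REAL; long best_d2 = 0;
  int bdx = 0, bdy = 0, bdz = 0; bool found = false;
  const int min_overlap = 8;

  for (int dx = slo[0]; dx <= shi[0]; ++dx)
    for (int dy = slo[1]; dy <= shi[1]; ++dy)
      for (int dz = slo[2]; dz <= shi[2]; ++dz) {
        double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0; long n = 0;
        for (int rx = tlo[0]; rx <= thi[0]; ++rx) {
          const int px = cx + rx, qx = cx + dx + rx;
          if (px < 0 || px >= pnx || qx < 0 || qx >= cnx) continue;
          for (int ry = tlo[1]; ry <= thi[1]; ++ry) {
            const int py = cy + ry, qy = cy + dy + ry;
            if (py < 0 || py >= pny || qy < 0 || qy >= cny) continue;
            for (int rz = tlo[2]; rz <= thi[2]; ++rz) {
              const int pz = cz + rz, qz = cz + dz + rz;
              if (pz < 0 || pz >= pnz || qz < 0 || qz >= cnz) continue;
              const double a =
                img_prev[px + (R_xlen_t)pnx * py + (R_xlen_t)pnx * pny * pz];
              const double b =
                img_cur[qx + (R_xlen_t)cnx * qy + (R_xlen_t)cnx * cny * qz];
              sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
              ++n;
            }
          }
        }
        if (n < min_overlap) continue;
        const double va = saa - sa * sa / n, vb = sbb - sb * sb / n;
        if (va <= 1e-12 || vb <= 1e-12) continue;  // flat patch: unmatchable here
        const double score = (sab - sa * sb / n) / std::sqrt(va * vb);
        const long d2 = (long)dx * dx + (long)dy * dy + (long)dz * dz;
        bool take = false;
        if (!found || score > best + 1e-12) {
          take = true;
        } else if (std::fabs(score - best) <= 1e-12) {
          if (d2 < best_d2) take = true;
          else if (d2 == best_d2) {
            if (dx < bdx || (dx == bdx && (dy < bdy || (dy == bdy && dz < bdz))))
              take = true;
          }
        }
        if (take) {
          best = score; best_d2 = d2; bdx = dx; bdy = dy; bdz = dz;
          found = true;
        }
      }

  if (!found)
    return List::create(_["found"] = false, _["best_ncc"] = 0.0,
                        _["best_pos"] = center);
  IntegerVector pos = IntegerVector::create(center[0] + bdx, center[1] + bdy,
                                            center[2] + bdz);
  return List::create(_["found"] = true, _["best_ncc"] = best,
                      _["best_pos"] = pos);
}
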