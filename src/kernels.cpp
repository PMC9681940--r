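#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Resample a 3D scalar grid onto an output grid.
// A is a 4x4 affine (column-major) mapping 0-based output voxel indices
// to 0-based continuous voxel indices of the moving grid. Trilinear by
// default; nearest-neighbour for label maps. Voxels whose 8-neighbourhood
// falls outside the moving grid get `fill` (may be NA for masking).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector mov, IntegerVector mdim,
                           IntegerVector odim, NumericVector A,
                           bool nearest, double fill) {
  const int mx = mdim[0], my = mdim[1], mz = mdim[2];
  const int ox = odim[0], oy = odim[1], oz = odim[2];
  const double a00 = A[0], a10 = A[1], a20 = A[2];
  const double a01 = A[4], a11 = A[5], a21 = A[6];
  const double a02 = A[8], a12 = A[9], a22 = A[10];
  const double a03 = A[12], a13 = A[13], a23 = A[14];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *m = mov.begin();
  double *o = out.begin();
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      const double bx = a01 * j + a02 * k + a03;
      const double by = a11 * j + a12 * k + a13;
      const double bz = a21 * j + a22 * k + a23;
      for (int i = 0; i < ox; ++i, ++idx) {
        const double u = a00 * i + bx;
        const double v = a10 * i + by;
        const double w = a20 * i + bz;
        if (nearest) {
          const int iu = (int)std::lround(u);
          const int iv = (int)std::lround(v);
          const int iw = (int)std::lround(w);
          if (iu < 0 || iv < 0 || iw < 0 || iu >= mx || iv >= my || iw >= mz)
            o[idx] = fill;
          else
            o[idx] = m[(R_xlen_t)iu + (R_xlen_t)mx * (iv + (R_xlen_t)my * iw)];
        } else {
          const double fu = std::floor(u), fv = std::floor(v), fw = std::floor(w);
          const int iu = (int)fu, iv = (int)fv, iw = (int)fw;
          if (iu < 0 || iv < 0 || iw < 0 ||
              iu + 1 >= mx || iv + 1 >= my || iw + 1 >= mz) {
            // allow exact upper-edge hits
            if (u >= 0 && v >= 0 && w >= 0 &&
                u <= mx - 1 && v <= my - 1 && w <= mz - 1) {
              const int cu = std::min(iu, mx - 2), cv = std::min(iv, my - 2),
                        cw = std::min(iw, mz - 2);
              const double du = u - cu, dv = v - cv, dw = w - cw;
              const R_xlen_t b = (R_xlen_t)cu + (R_xlen_t)mx * (cv + (R_xlen_t)my * cw);
              const R_xlen_t sx = 1, sy = mx, sz = (R_xlen_t)mx * my;
              const double c00 = m[b] * (1 - du) + m[b + sx] * du;
              const double c10 = m[b + sy] * (1 - du) + m[b + sy + sx] * du;
              const double c01 = m[b + sz] * (1 - du) + m[b + sz + sx] * du;
              const double c11 = m[b + sz + sy] * (1 - du) + m[b + sz + sy + sx] * du;
              o[idx] = (c00 * (1 - dv) + c10 * dv) * (1 - dw) +
                       (c01 * (1 - dv) + c11 * dv) * dw;
            } else {
              o[idx] = fill;
            }
          } else {
            const double du = u - fu, dv = v - fv, dw = w - fw;
            const R_xlen_t b = (R_xlen_t)iu + (R_xlen_t)mx * (iv + (R_xlen_t)my * iw);
            const R_xlen_t sx = 1, sy = mx, sz = (R_xlen_t)mx * my;
            const double c00 = m[b] * (1 - du) + m[b + sx] * du;
            const double c10 = m[b + sy] * (1 - du) + m[b + sy + sx] * du;
            const double c01 = m[b + sz] * (1 - du) + m[b + sz + sx] * du;
            const double c11 = m[b + sz + sy] * (1 - du) + m[b + sz + sy + sx] * du;
            o[idx] = (c00 * (1 - dv) + c10 * dv) * (1 - dw) +
                     (c01 * (1 - dv) + c11 * dv) * dw;
          }
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a 3D binary mask, 26-connectivity.
// Components are numbered 1..n in order of their first voxel in
// column-major scan order, so labels are independent of any hash or
// recursion order and fully deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int *msk = LOGICAL(mask);
  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (msk[s] != 1 || lab[s] != 0) continue;
    ++current;
    stack.clear();
    stack.push_back(s);
    lab[s] = current;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int pi = (int)(p % nx);
      const int pj = (int)((p / nx) % ny);
      const int pk = (int)(p / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk) {
        const int qk = pk + dk;
        if (qk < 0 || qk >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          const int qj = pj + dj;
          if (qj < 0 || qj >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            const int qi = pi + di;
            if (qi < 0 || qi >= nx) continue;
            const R_xlen_t q = (R_xlen_t)qi + (R_xlen_t)nx * (qj + (R_xlen_t)ny * qk);
            if (msk[q] == 1 && lab[q] == 0) {
              lab[q] = current;
              stack.push_back(q);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = current;
  return lab;
}
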