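#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Resample a 3D volume onto a target grid through an affine voxel map.
// M maps target 0-based voxel coordinates to source 0-based voxel
// coordinates (homogeneous 4x4). interp: 0 = nearest neighbour,
// 1 = trilinear. Samples outside the source grid take `background`
// (may be NA to mark invalid samples for registration masking).
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericMatrix M, IntegerVector tdim,
                                  int interp, double background) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  const double *s = src.begin();
  double *o = out.begin();
  const double m00 = M(0,0), m01 = M(0,1), m02 = M(0,2), m03 = M(0,3);
  const double m10 = M(1,0), m11 = M(1,1), m12 = M(1,2), m13 = M(1,3);
  const double m20 = M(2,0), m21 = M(2,1), m22 = M(2,2), m23 = M(2,3);
  R_xlen_t v = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      for (int i = 0; i < tx; ++i, ++v) {
        const double xs = m00*i + m01*j + m02*k + m03;
        const double ys = m10*i + m11*j + m12*k + m13;
        const double zs = m20*i + m21*j + m22*k + m23;
        if (interp == 0) {
          const int ix = (int)std::lround(xs);
          const int iy = (int)std::lround(ys);
          const int iz = (int)std::lround(zs);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= sx || iy >= sy || iz >= sz) {
            o[v] = background;
          } else {
            o[v] = s[(R_xlen_t)ix + (R_xlen_t)sx * (iy + (R_xlen_t)sy * iz)];
          }
        } else {
          const int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys),
                    z0 = (int)std::floor(zs);
          if (x0 < 0 || y0 < 0 || z0 < 0 ||
              x0 + 1 >= sx || y0 + 1 >= sy || z0 + 1 >= sz) {
            o[v] = background;
          } else {
            const double fx = xs - x0, fy = ys - y0, fz = zs - z0;
            const R_xlen_t b = (R_xlen_t)x0 + (R_xlen_t)sx * (y0 + (R_xlen_t)sy * z0);
            const R_xlen_t dy = sx, dz = (R_xlen_t)sx * sy;
            const double c000 = s[b],            c100 = s[b + 1];
            const double c010 = s[b + dy],       c110 = s[b + 1 + dy];
            const double c001 = s[b + dz],       c101 = s[b + 1 + dz];
            const double c011 = s[b + dy + dz],  c111 = s[b + 1 + dy + dz];
            const double c00 = c000 * (1 - fx) + c100 * fx;
            const double c10 = c010 * (1 - fx) + c110 * fx;
            const double c01 = c001 * (1 - fx) + c101 * fx;
            const double c11 = c011 * (1 - fx) + c111 * fx;
            const double c0 = c00 * (1 - fy) + c10 * fy;
            const double c1 = c01 * (1 - fy) + c11 * fy;
            o[v] = c0 * (1 - fz) + c1 * fz;
          }
        }
      }
    }
  }
  return out;
}
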