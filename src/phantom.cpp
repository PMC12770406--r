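#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Implicit solid model of the two-segment cervix phantom.
//
// The canal is the set of points within canal_r of the two-segment
// centreline (inlet-mid, mid-outlet; point-to-segment distance, so the
// elbow is rounded), cut by flat planes through the inlet and outlet
// perpendicular to the respective segment, giving clean open ends that
// touch background. The inner and outer stroma are concentric shells of
// the same cut construction. Cyst spheres overwrite canal voxels; the
// bladder sphere is drawn only where background remains.

struct PhantomGeom {
  double in[3], mid[3], out[3];     // centreline points, world mm
  double u1[3], u2[3];              // unit vectors mid->inlet, mid->outlet
  double canal_r, r_inner, r_outer; // canal radius and shell outer radii
  int n_cyst;
  const double *cyst_c;             // 3 x n_cyst column-major (R matrix)
  const double *cyst_r;
  bool has_bladder;
  double bl_c[3], bl_r;
};

static inline double dist_seg2(const double p[3], const double a[3],
                               const double b[3]) {
  const double abx = b[0]-a[0], aby = b[1]-a[1], abz = b[2]-a[2];
  const double apx = p[0]-a[0], apy = p[1]-a[1], apz = p[2]-a[2];
  const double denom = abx*abx + aby*aby + abz*abz;
  double t = denom > 0 ? (apx*abx + apy*aby + apz*abz) / denom : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double dx = apx - t*abx, dy = apy - t*aby, dz = apz - t*abz;
  return dx*dx + dy*dy + dz*dz;
}

static PhantomGeom make_geom(const NumericVector &inlet, const NumericVector &mid,
                             const NumericVector &outlet, double canal_r,
                             double t_inner, double t_outer,
                             const NumericMatrix &cyst_centres,
                             const NumericVector &cyst_radii,
                             const NumericVector &bladder_centre,
                             double bladder_radius) {
  PhantomGeom g;
  for (int d = 0; d < 3; ++d) {
    g.in[d] = inlet[d]; g.mid[d] = mid[d]; g.out[d] = outlet[d];
  }
  double n1 = 0, n2 = 0;
  for (int d = 0; d < 3; ++d) {
    g.u1[d] = g.in[d] - g.mid[d]; n1 += g.u1[d]*g.u1[d];
    g.u2[d] = g.out[d] - g.mid[d]; n2 += g.u2[d]*g.u2[d];
  }
  n1 = std::sqrt(n1); n2 = std::sqrt(n2);
  for (int d = 0; d < 3; ++d) { g.u1[d] /= n1; g.u2[d] /= n2; }
  g.canal_r = canal_r;
  g.r_inner = canal_r + t_inner;
  g.r_outer = canal_r + t_inner + t_outer;
  g.n_cyst = cyst_radii.size();
  g.cyst_c = g.n_cyst > 0 ? &cyst_centres(0, 0) : nullptr;
  g.cyst_r = g.n_cyst > 0 ? &cyst_radii[0] : nullptr;
  g.has_bladder = bladder_radius > 0;
  if (g.has_bladder) {
    for (int d = 0; d < 3; ++d) g.bl_c[d] = bladder_centre[d];
  }
  g.bl_r = bladder_radius;
  return g;
}

static inline int classify_point(const double p[3], const PhantomGeom &g) {
  // outside the flat end caps -> not part of the cervix solid
  const double cap_in = (p[0]-g.in[0])*g.u1[0] + (p[1]-g.in[1])*g.u1[1] +
                        (p[2]-g.in[2])*g.u1[2];
  const double cap_out = (p[0]-g.out[0])*g.u2[0] + (p[1]-g.out[1])*g.u2[1] +
                         (p[2]-g.out[2])*g.u2[2];
  bool in_caps = (cap_in <= 0 && cap_out <= 0);
  if (in_caps) {
    const double d2 = std::min(dist_seg2(p, g.in, g.mid),
                               dist_seg2(p, g.mid, g.out));
    if (d2 <= g.canal_r * g.canal_r) {
      for (int c = 0; c < g.n_cyst; ++c) {
        const double dx = p[0] - g.cyst_c[3*c], dy = p[1] - g.cyst_c[3*c+1],
                     dz = p[2] - g.cyst_c[3*c+2];
        if (dx*dx + dy*dy + dz*dz <= g.cyst_r[c]*g.cyst_r[c]) return 4;
      }
      return 1;
    }
    if (d2 <= g.r_inner * g.r_inner) return 2;
    if (d2 <= g.r_outer * g.r_outer) return 3;
  }
  if (g.has_bladder) {
    const double dx = p[0]-g.bl_c[0], dy = p[1]-g.bl_c[1], dz = p[2]-g.bl_c[2];
    if (dx*dx + dy*dy + dz*dz <= g.bl_r*g.bl_r) return 5;
  }
  return 0;
}

// Rasterize the phantom onto a voxel grid by supersampled majority vote:
// each voxel is classified at ss^3 stratified sample points; ties are
// broken by label priority cyst > canal > inner > outer > bladder >
// background.
// [[Rcpp::export]]
IntegerVector phantom_rasterize_cpp(IntegerVector dims, NumericMatrix affine,
                                    int ss,
                                    NumericVector inlet, NumericVector mid,
                                    NumericVector outlet,
                                    double canal_r, double t_inner, double t_outer,
                                    NumericMatrix cyst_centres,
                                    NumericVector cyst_radii,
                                    NumericVector bladder_centre,
                                    double bladder_radius) {
  const PhantomGeom g = make_geom(inlet, mid, outlet, canal_r, t_inner, t_outer,
                                  cyst_centres, cyst_radii, bladder_centre,
                                  bladder_radius);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out((R_xlen_t)nx * ny * nz);
  int *o = out.begin();
  const double a00 = affine(0,0), a01 = affine(0,1), a02 = affine(0,2), a03 = affine(0,3);
  const double a10 = affine(1,0), a11 = affine(1,1), a12 = affine(1,2), a13 = affine(1,3);
  const double a20 = affine(2,0), a21 = affine(2,1), a22 = affine(2,2), a23 = affine(2,3);
  const int prio[6] = {4, 1, 2, 3, 5, 0}; // tie-break priority order
  std::vector<double> offs(ss);
  for (int s = 0; s < ss; ++s) offs[s] = (s + 0.5) / ss - 0.5;

  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++v) {
        int counts[6] = {0, 0, 0, 0, 0, 0};
        for (int sz = 0; sz < ss; ++sz)
          for (int sy = 0; sy < ss; ++sy)
            for (int sx = 0; sx < ss; ++sx) {
              const double xi = i + offs[sx], yj = j + offs[sy], zk = k + offs[sz];
              const double p[3] = {a00*xi + a01*yj + a02*zk + a03,
                                   a10*xi + a11*yj + a12*zk + a13,
                                   a20*xi + a21*yj + a22*zk + a23};
              ++counts[classify_point(p, g)];
            }
        int best = 0, best_count = -1;
        for (int q = 0; q < 6; ++q) {
          const int lab = prio[q];
          if (counts[lab] > best_count) { best = lab; best_count = counts[lab]; }
        }
        o[v] = best;
      }
    }
  }
  return out;
}

// Numerical label volumes of the implicit solid: uniform point sampling at
// `step` mm over the world-aligned bounding box [lo, hi]. Returns the
// sampled volume in mm^3 for labels 1..5. Used as the geometric oracle for
// bent phantoms where no simple closed form exists.
// [[Rcpp::export]]
NumericVector phantom_sample_volumes_cpp(NumericVector lo, NumericVector hi,
                                         double step,
                                         NumericVector inlet, NumericVector mid,
                                         NumericVector outlet,
                                         double canal_r, double t_inner,
                                         double t_outer,
                                         NumericMatrix cyst_centres,
                                         NumericVector cyst_radii,
                                         NumericVector bladder_centre,
                                         double bladder_radius) {
  const PhantomGeom g = make_geom(inlet, mid, outlet, canal_r, t_inner, t_outer,
                                  cyst_centres, cyst_radii, bladder_centre,
                                  bladder_radius);
  const int nx = (int)std::ceil((hi[0] - lo[0]) / step);
  const int ny = (int)std::ceil((hi[1] - lo[1]) / step);
  const int nz = (int)std::ceil((hi[2] - lo[2]) / step);
  std::vector<R_xlen_t> counts(6, 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const double p[3] = {lo[0] + (i + 0.5) * step,
                             lo[1] + (j + 0.5) * step,
                             lo[2] + (k + 0.5) * step};
        ++counts[classify_point(p, g)];
      }
  const double dv = step * step * step;
  NumericVector out(5);
  for (int lab = 1; lab <= 5; ++lab) out[lab - 1] = counts[lab] * dv;
  return out;
}
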