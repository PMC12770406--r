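#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling of a 3D logical mask with 6- or
// 26-connectivity. Returns an integer array of component ids (0 where
// the mask is FALSE); ids are assigned in scan order and are stable.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(n, 0);
  const int *m = mask.begin();
  int *c = comp.begin();

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int noff = (int)offx.size();

  std::vector<R_xlen_t> stack;
  int next_id = 0;
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!m[v] || c[v] != 0) continue;
    ++next_id;
    stack.clear();
    stack.push_back(v);
    c[v] = next_id;
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = (int)(cur % nx);
      const int y = (int)((cur / nx) % ny);
      const int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (int o = 0; o < noff; ++o) {
        const int xx = x + offx[o], yy = y + offy[o], zz = z + offz[o];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (m[w] && c[w] == 0) {
          c[w] = next_id;
          stack.push_back(w);
        }
      }
    }
  }
  comp.attr("n_components") = next_id;
  return comp;
}
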