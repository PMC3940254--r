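#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by flood fill. 2-D masks use 4- or
// 8-connectivity (8 is the microscopy convention here); 3-D grids use 6- or
// 26-connectivity (26 for the PET isocontour component rule).

// [[Rcpp::export(name = ".label_components_2d_cpp")]]
IntegerMatrix label_components_2d(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const bool diag = (connectivity == 8);
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        int r = v % nr, c = v / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            if (!diag && dr != 0 && dc != 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// [[Rcpp::export(name = ".label_components_3d_cpp")]]
IntegerVector label_components_3d(IntegerVector mask, IntegerVector dims,
                                  int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<int> stack;
  const bool diag = (connectivity == 26);
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int v0 = x0 + nx * (y0 + ny * z0);
        if (mask[v0] == 0 || lab[v0] != 0) continue;
        ++next;
        stack.clear();
        stack.push_back(v0);
        lab[v0] = next;
        while (!stack.empty()) {
          int v = stack.back(); stack.pop_back();
          int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (dx == 0 && dy == 0 && dz == 0) continue;
                if (!diag && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
                  continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                  continue;
                int w = xx + nx * (yy + ny * zz);
                if (mask[w] != 0 && lab[w] == 0) {
                  lab[w] = next;
                  stack.push_back(w);
                }
              }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}
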