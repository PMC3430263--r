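#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Mark voxels lying within `radius` of any heavy atom.
// Voxel centre (i,j,k) sits at origin + spacing * (i,j,k), 0-based.
// [[Rcpp::export]]
LogicalVector cpp_mark_occupancy(IntegerVector dims, NumericVector origin,
                                 double spacing, NumericMatrix coords,
                                 double radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector occ(nx * (R_xlen_t)ny * nz, false);
  const double r2 = radius * radius;
  const int reach = (int)std::ceil(radius / spacing);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const int ci = (int)std::floor((ax - origin[0]) / spacing + 0.5);
    const int cj = (int)std::floor((ay - origin[1]) / spacing + 0.5);
    const int ck = (int)std::floor((az - origin[2]) / spacing + 0.5);
    for (int i = std::max(0, ci - reach); i <= std::min(nx - 1, ci + reach); ++i) {
      const double dx = origin[0] + spacing * i - ax;
      for (int j = std::max(0, cj - reach); j <= std::min(ny - 1, cj + reach); ++j) {
        const double dy = origin[1] + spacing * j - ay;
        for (int k = std::max(0, ck - reach); k <= std::min(nz - 1, ck + reach); ++k) {
          const double dz = origin[2] + spacing * k - az;
          if (dx * dx + dy * dy + dz * dz <= r2)
            occ[idx3(i, j, k, nx, ny)] = true;
        }
      }
    }
  }
  return occ;
}

// Protein-solvent-protein events along 7 scan axes (x, y, z and the four
// cube diagonals). A solvent voxel scores one event per axis along which a
// protein voxel exists on BOTH sides.
// [[Rcpp::export]]
IntegerVector cpp_scan_psp(LogicalVector occ, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int dirs[7][3] = {
    {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
    {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {-1, 1, 1}
  };
  IntegerVector psp(occ.size(), 0);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        if (occ[v]) { psp[v] = NA_INTEGER; continue; }
        int count = 0;
        for (int d = 0; d < 7; ++d) {
          bool fwd = false, bwd = false;
          int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
          while (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) {
            if (occ[idx3(ii, jj, kk, nx, ny)]) { fwd = true; break; }
            ii += dirs[d][0]; jj += dirs[d][1]; kk += dirs[d][2];
          }
          if (!fwd) continue;
          ii = i - dirs[d][0]; jj = j - dirs[d][1]; kk = k - dirs[d][2];
          while (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) {
            if (occ[idx3(ii, jj, kk, nx, ny)]) { bwd = true; break; }
            ii -= dirs[d][0]; jj -= dirs[d][1]; kk -= dirs[d][2];
          }
          if (bwd) ++count;
        }
        psp[v] = count;
      }
  return psp;
}

// 26-connected component labelling of a voxel mask (BFS). Labels are
// 1..K in discovery order; 0 = background. Callers re-order by size.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const int v = idx3(i, j, k, nx, ny);
        if (!mask[v] || lab[v] != 0) continue;
        lab[v] = ++next;
        q.push(v);
        while (!q.empty()) {
          const int u = q.front(); q.pop();
          const int uk = u / (nx * ny), uj = (u / nx) % ny, ui = u % nx;
          for (int di = -1; di <= 1; ++di)
            for (int dj = -1; dj <= 1; ++dj)
              for (int dk = -1; dk <= 1; ++dk) {
                if (!di && !dj && !dk) continue;
                const int wi = ui + di, wj = uj + dj, wk = uk + dk;
                if (wi < 0 || wi >= nx || wj < 0 || wj >= ny || wk < 0 || wk >= nz)
                  continue;
                const int w = idx3(wi, wj, wk, nx, ny);
                if (mask[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
              }
        }
      }
  return lab;
}
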