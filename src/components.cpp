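#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static int findRoot(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  int ra = findRoot(parent, a), rb = findRoot(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Label maximal connected components of a 3D logical/0-1 array under
// 6/18/26 connectivity. Returns an integer array of the same shape with
// components numbered from 1 (0 = background).
// [[Rcpp::export(name = ".labelComponents")]]
IntegerVector labelComponents(LogicalVector mask, IntegerVector dims,
                              int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> parent(n);
  for (R_xlen_t i = 0; i < n; ++i) parent[i] = (int)i;

  // Scan only "backward" neighbor offsets so each pair is visited once.
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = (R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
        if (!mask[idx]) continue;
        for (int dz = -1; dz <= 0; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0))) continue;
              int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
              if (manh == 0) continue;
              if (connectivity == 6 && manh > 1) continue;
              if (connectivity == 18 && manh > 2) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0)
                continue;
              R_xlen_t idx2 =
                  (R_xlen_t)x2 + nx * ((R_xlen_t)y2 + (R_xlen_t)ny * z2);
              if (mask[idx2]) unite(parent, (int)idx, (int)idx2);
            }
      }

  IntegerVector out(n, 0);
  std::vector<int> relabel(n, 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i]) continue;
    int r = findRoot(parent, (int)i);
    if (relabel[r] == 0) relabel[r] = ++next;
    out[i] = relabel[r];
  }
  out.attr("dim") = dims;
  return out;
}
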