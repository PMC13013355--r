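#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

// 3D connected-component labelling on a column-major integer grid.
// Two voxels are connected when they are adjacent under the requested
// neighbourhood (6 faces, 18 faces+edges, 26 full) AND carry the same
// positive value, so instance masks keep touching instances separate
// while binary masks decompose into components. Labels are assigned in
// scan order of each component's first voxel (x fastest), which fixes a
// deterministic lesion ordering.
// [[Rcpp::export]]
IntegerVector cc_label3d(IntegerVector mask, IntegerVector dims, int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] <= 0 || lab[i] != 0) continue;
    const int val = mask[i];
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      const int x = (int)(j % nx);
      const int y = (int)((j / nx) % ny);
      const int z = (int)(j / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dxs.size(); ++k) {
        const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        const R_xlen_t jj = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[jj] == val && lab[jj] == 0) {
          lab[jj] = next;
          stack.push_back(jj);
        }
      }
    }
  }
  return lab;
}

// 32-bit FNV-1a hash of a raw byte vector, returned as a double so it
// survives JSON round trips. Used for manifest checksums and config
// fingerprints (provenance, not cryptography).
// [[Rcpp::export]]
double fnv1a32(RawVector bytes) {
  uint32_t h = 2166136261u;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint32_t)bytes[i];
    h *= 16777619u;
  }
  return (double)h;
}
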