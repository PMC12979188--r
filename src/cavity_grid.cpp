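#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Interior-cavity volume on a regular grid.
//
// A voxel is "blocked" when its centre lies inside any atom sphere inflated
// by the probe radius. Free voxels 6-connected to the bounding-box exterior
// are solvent; the remaining free voxels are interior cavities. The grid
// origin is tied to the structure's own bounding box, so the result is
// exactly invariant to rigid translation and to axis permutation.
//
// [[Rcpp::export]]
List cpp_cavity_volume(NumericMatrix coords, NumericVector radii,
                       double probe, double spacing) {
  const int n = coords.nrow();
  if (n < 1) stop("empty structure: no atoms");
  if (spacing <= 0) stop("grid_spacing must be > 0");
  if (radii.size() != n) stop("one radius per atom required");

  // bounding box of inflated atoms, padded by one voxel layer so the
  // exterior is always connected around the structure
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i) {
    double r = radii[i] + probe;
    for (int d = 0; d < 3; ++d) {
      if (coords(i, d) - r < lo[d]) lo[d] = coords(i, d) - r;
      if (coords(i, d) + r > hi[d]) hi[d] = coords(i, d) + r;
    }
  }
  for (int d = 0; d < 3; ++d) { lo[d] -= 2.0 * spacing; hi[d] += 2.0 * spacing; }

  int dim[3];
  for (int d = 0; d < 3; ++d) {
    dim[d] = (int)std::ceil((hi[d] - lo[d]) / spacing);
    if (dim[d] < 3) dim[d] = 3;
  }
  const long nx = dim[0], ny = dim[1], nz = dim[2];
  const long nvox = nx * ny * nz;
  if (nvox > 400000000L) stop("grid too large; increase grid_spacing");

  // 0 = free, 1 = blocked, 2 = exterior
  std::vector<unsigned char> state(nvox, 0);
  const long sx = 1, sy = nx, sz = nx * ny;

  // rasterise atoms: mark voxels whose centre is within radius+probe
  for (int i = 0; i < n; ++i) {
    const double r = radii[i] + probe, r2 = r * r;
    const double ax = coords(i, 0), ay = coords(i, 1), az = coords(i, 2);
    int i0[3], i1[3];
    const double c[3] = {ax, ay, az};
    for (int d = 0; d < 3; ++d) {
      i0[d] = (int)std::floor((c[d] - r - lo[d]) / spacing - 0.5);
      i1[d] = (int)std::ceil((c[d] + r - lo[d]) / spacing - 0.5);
      if (i0[d] < 0) i0[d] = 0;
      if (i1[d] > dim[d] - 1) i1[d] = dim[d] - 1;
    }
    for (int iz = i0[2]; iz <= i1[2]; ++iz) {
      const double dz = lo[2] + (iz + 0.5) * spacing - az;
      for (int iy = i0[1]; iy <= i1[1]; ++iy) {
        const double dy = lo[1] + (iy + 0.5) * spacing - ay;
        const double dyz2 = dy * dy + dz * dz;
        if (dyz2 > r2) continue;
        for (int ix = i0[0]; ix <= i1[0]; ++ix) {
          const double dx = lo[0] + (ix + 0.5) * spacing - ax;
          if (dx * dx + dyz2 <= r2)
            state[ix * sx + iy * sy + iz * sz] = 1;
        }
      }
    }
  }

  // flood fill (6-connected) from every free boundary voxel
  std::vector<long> stack;
  stack.reserve(1 << 16);
  for (long iz = 0; iz < nz; ++iz)
    for (long iy = 0; iy < ny; ++iy)
      for (long ix = 0; ix < nx; ++ix) {
        if (ix > 0 && ix < nx - 1 && iy > 0 && iy < ny - 1 &&
            iz > 0 && iz < nz - 1) continue;
        long v = ix * sx + iy * sy + iz * sz;
        if (state[v] == 0) { state[v] = 2; stack.push_back(v); }
      }
  while (!stack.empty()) {
    long v = stack.back();
    stack.pop_back();
    long ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
    const long nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
    const bool ok[6] = {ix > 0, ix < nx - 1, iy > 0, iy < ny - 1,
                        iz > 0, iz < nz - 1};
    for (int k = 0; k < 6; ++k)
      if (ok[k] && state[nb[k]] == 0) { state[nb[k]] = 2; stack.push_back(nb[k]); }
  }

  long n_cavity = 0, n_blocked = 0;
  for (long v = 0; v < nvox; ++v) {
    if (state[v] == 0) ++n_cavity;
    else if (state[v] == 1) ++n_blocked;
  }
  const double vol = (double)n_cavity * spacing * spacing * spacing;

  return List::create(
    _["volume"] = vol,
    _["n_cavity_voxels"] = (double)n_cavity,
    _["n_blocked_voxels"] = (double)n_blocked,
    _["dims"] = IntegerVector::create(dim[0], dim[1], dim[2]));
}
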