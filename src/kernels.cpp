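#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

// Point-in-closed-surface classification of a voxel grid by ray parity.
// Rays run along +x through every voxel center; the ray origin is offset by a
// tiny fixed fraction of the spacing in y and z so that hits on triangle
// edges/vertices (which sit on lattice half-planes) cannot occur. The offset
// is deterministic, so classification is reproducible bit-for-bit.
//
// V: n x 3 vertex coordinates (mm), F: m x 3 one-based vertex indices.
// Grid: origin (x0,y0,z0) = lower corner, spacing (dx,dy,dz), dims (nx,ny,nz).
// Returns an integer vector of length nx*ny*nz (x fastest), 1 = inside.
// [[Rcpp::export]]
IntegerVector cpp_classify_parity(NumericMatrix V, IntegerMatrix F,
                                  double x0, double dx, int nx,
                                  double y0, double dy, int ny,
                                  double z0, double dz, int nz) {
  const double eps_y = 1.3e-5 * dy, eps_z = 2.9e-5 * dz;
  const int nray = ny * nz;
  std::vector< std::vector<double> > cross(nray);

  const int m = F.nrow();
  for (int t = 0; t < m; ++t) {
    const int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
    const double ax = V(ia,0), ay = V(ia,1), az = V(ia,2);
    const double bx = V(ib,0), by = V(ib,1), bz = V(ib,2);
    const double cx = V(ic,0), cy = V(ic,1), cz = V(ic,2);
    // projected triangle in (y,z)
    const double det = (by - ay) * (cz - az) - (bz - az) * (cy - ay);
    const double scale = std::max({std::abs(by-ay), std::abs(bz-az),
                                   std::abs(cy-ay), std::abs(cz-az), 1e-300});
    if (std::abs(det) < 1e-14 * scale * scale) continue;  // edge-on to ray
    const double ylo = std::min({ay, by, cy}), yhi = std::max({ay, by, cy});
    const double zlo = std::min({az, bz, cz}), zhi = std::max({az, bz, cz});
    int j0 = (int)std::ceil ((ylo - eps_y - y0) / dy - 0.5);
    int j1 = (int)std::floor((yhi - eps_y - y0) / dy - 0.5);
    int k0 = (int)std::ceil ((zlo - eps_z - z0) / dz - 0.5);
    int k1 = (int)std::floor((zhi - eps_z - z0) / dz - 0.5);
    j0 = std::max(j0, 0); j1 = std::min(j1, ny - 1);
    k0 = std::max(k0, 0); k1 = std::min(k1, nz - 1);
    for (int k = k0; k <= k1; ++k) {
      const double pz = z0 + (k + 0.5) * dz + eps_z;
      for (int j = j0; j <= j1; ++j) {
        const double py = y0 + (j + 0.5) * dy + eps_y;
        // barycentric in the (y,z) projection
        const double wb = ((py - ay) * (cz - az) - (pz - az) * (cy - ay)) / det;
        const double wc = ((by - ay) * (pz - az) - (bz - az) * (py - ay)) / det;
        const double wa = 1.0 - wb - wc;
        if (wa < 0.0 || wb < 0.0 || wc < 0.0) continue;
        cross[j + (size_t)k * ny].push_back(wa * ax + wb * bx + wc * cx);
      }
    }
  }

  IntegerVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<double>& xs = cross[j + (size_t)k * ny];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      size_t pos = 0;
      int parity = 0;
      for (int i = 0; i < nx; ++i) {
        const double xc = x0 + (i + 0.5) * dx;
        while (pos < xs.size() && xs[pos] < xc) { parity ^= 1; ++pos; }
        if (parity) out[(R_xlen_t)i + (R_xlen_t)j * nx + (R_xlen_t)k * nx * ny] = 1;
      }
    }
  }
  return out;
}

// 6-connected component labelling of a binary mask (x fastest ordering).
// Returns integer labels 1..ncomp, 0 for background.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int nx, int ny, int nz) {
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx * ny));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int i2 = i + di[d], j2 = j + dj[d], k2 = k + dk[d];
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz) continue;
        R_xlen_t w = (R_xlen_t)i2 + (R_xlen_t)j2 * nx + (R_xlen_t)k2 * nx * ny;
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  lab.attr("ncomp") = next;
  return lab;
}
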