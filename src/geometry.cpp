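#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Deterministic unit-sphere point set (Fibonacci / golden-spiral lattice).
static std::vector<double> sphere_points(int n) {
  std::vector<double> pts(3 * n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * i;
    pts[3 * i] = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
  return pts;
}

// Shrake-Rupley solvent-accessible surface area per atom.
// xyz: n x 3, radii: vdW radii, probe: solvent radius, n_points: test points.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  int n = xyz.nrow();
  NumericVector area(n);
  std::vector<double> pts = sphere_points(n_points);
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;
  for (int i = 0; i < n; ++i) {
    double ri = er[i];
    // neighbour list; of two exactly coincident atoms the lower index keeps
    // its surface (the union of the spheres is a single sphere)
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 1e-12 && er[j] <= ri && j > i) continue;
      double lim = ri + er[j];
      if (d2 < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = xyz(i, 0) + ri * pts[3 * p];
      double py = xyz(i, 1) + ri * pts[3 * p + 1];
      double pz = xyz(i, 2) + ri * pts[3 * p + 2];
      bool buried = false;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        // <= with slack so a point exactly on a neighbour's surface
        // (fully coincident atoms) counts as buried
        if (dx * dx + dy * dy + dz * dz <= er[j] * er[j] + 1e-9) {
          buried = true; break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}

// Volume of the union of atom spheres by voxel counting at grid spacing g.
// [[Rcpp::export(name = ".voxel_volume_cpp")]]
double voxel_volume_cpp(NumericMatrix xyz, NumericVector radii, double g) {
  int n = xyz.nrow();
  if (n == 0) return 0.0;
  double rmax = 0.0;
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i) {
    if (radii[i] > rmax) rmax = radii[i];
    for (int d = 0; d < 3; ++d) {
      if (xyz(i, d) < lo[d]) lo[d] = xyz(i, d);
      if (xyz(i, d) > hi[d]) hi[d] = xyz(i, d);
    }
  }
  for (int d = 0; d < 3; ++d) { lo[d] -= rmax + g; hi[d] += rmax + g; }
  long nx = (long)std::ceil((hi[0] - lo[0]) / g) + 1;
  long ny = (long)std::ceil((hi[1] - lo[1]) / g) + 1;
  long nz = (long)std::ceil((hi[2] - lo[2]) / g) + 1;
  std::vector<char> filled((size_t)nx * ny * nz, 0);
  for (int i = 0; i < n; ++i) {
    double r = radii[i], r2 = r * r;
    long ix0 = (long)std::floor((xyz(i, 0) - r - lo[0]) / g);
    long ix1 = (long)std::ceil((xyz(i, 0) + r - lo[0]) / g);
    long iy0 = (long)std::floor((xyz(i, 1) - r - lo[1]) / g);
    long iy1 = (long)std::ceil((xyz(i, 1) + r - lo[1]) / g);
    long iz0 = (long)std::floor((xyz(i, 2) - r - lo[2]) / g);
    long iz1 = (long)std::ceil((xyz(i, 2) + r - lo[2]) / g);
    if (ix0 < 0) ix0 = 0; if (iy0 < 0) iy0 = 0; if (iz0 < 0) iz0 = 0;
    if (ix1 >= nx) ix1 = nx - 1;
    if (iy1 >= ny) iy1 = ny - 1;
    if (iz1 >= nz) iz1 = nz - 1;
    for (long ix = ix0; ix <= ix1; ++ix) {
      double dx = lo[0] + (ix + 0.5) * g - xyz(i, 0);
      for (long iy = iy0; iy <= iy1; ++iy) {
        double dy = lo[1] + (iy + 0.5) * g - xyz(i, 1);
        double dxy = dx * dx + dy * dy;
        if (dxy > r2) continue;
        for (long iz = iz0; iz <= iz1; ++iz) {
          double dz = lo[2] + (iz + 0.5) * g - xyz(i, 2);
          if (dxy + dz * dz <= r2)
            filled[(size_t)(ix * ny + iy) * nz + iz] = 1;
        }
      }
    }
  }
  size_t count = 0;
  for (size_t k = 0; k < filled.size(); ++k) count += filled[k];
  return count * g * g * g;
}
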