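#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Area of the union of disks on a raster grid of cell size `res`.
// Cell counts as covered when its centre lies inside at least one disk.
static double raster_union_area(const std::vector<double>& px,
                                const std::vector<double>& py,
                                const std::vector<double>& r,
                                double res) {
  const int n = px.size();
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, px[i] - r[i]);
    xmax = std::max(xmax, px[i] + r[i]);
    ymin = std::min(ymin, py[i] - r[i]);
    ymax = std::max(ymax, py[i] + r[i]);
  }
  const int nx = std::max(1, (int)std::ceil((xmax - xmin) / res));
  const int ny = std::max(1, (int)std::ceil((ymax - ymin) / res));
  std::vector<char> hit((size_t)nx * ny, 0);
  for (int i = 0; i < n; ++i) {
    const double r2 = r[i] * r[i];
    int ix0 = std::max(0, (int)std::floor((px[i] - r[i] - xmin) / res) - 1);
    int ix1 = std::min(nx - 1, (int)std::ceil((px[i] + r[i] - xmin) / res) + 1);
    int iy0 = std::max(0, (int)std::floor((py[i] - r[i] - ymin) / res) - 1);
    int iy1 = std::min(ny - 1, (int)std::ceil((py[i] + r[i] - ymin) / res) + 1);
    for (int ix = ix0; ix <= ix1; ++ix) {
      const double dx = xmin + (ix + 0.5) * res - px[i];
      const double dx2 = dx * dx;
      if (dx2 > r2) continue;
      for (int iy = iy0; iy <= iy1; ++iy) {
        const double dy = ymin + (iy + 0.5) * res - py[i];
        if (dx2 + dy * dy <= r2) hit[(size_t)ix * ny + iy] = 1;
      }
    }
  }
  size_t count = 0;
  for (size_t k = 0; k < hit.size(); ++k) count += hit[k];
  return (double)count * res * res;
}

// Projected union-of-disks area along each direction (rows of `dirs`,
// assumed unit vectors). Atoms are projected onto the plane normal to
// the direction; vdW radii are unchanged by the orthogonal projection.
// [[Rcpp::export]]
NumericVector cpp_projection_areas(NumericMatrix pos, NumericVector radii,
                                   NumericMatrix dirs, double res) {
  const int natom = pos.nrow();
  const int ndir = dirs.nrow();
  if (radii.size() != natom) stop("radii length must match atom count");
  if (res <= 0) stop("resolution must be > 0");
  NumericVector out(ndir);
  std::vector<double> px(natom), py(natom), rr(radii.begin(), radii.end());
  for (int d = 0; d < ndir; ++d) {
    double dx = dirs(d, 0), dy = dirs(d, 1), dz = dirs(d, 2);
    // orthonormal in-plane basis (u, v)
    double ax, ay, az;
    if (std::fabs(dz) < 0.9) { ax = 0; ay = 0; az = 1; }
    else { ax = 1; ay = 0; az = 0; }
    double ux = dy * az - dz * ay, uy = dz * ax - dx * az, uz = dx * ay - dy * ax;
    double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    double vx = dy * uz - dz * uy, vy = dz * ux - dx * uz, vz = dx * uy - dy * ux;
    for (int i = 0; i < natom; ++i) {
      px[i] = pos(i, 0) * ux + pos(i, 1) * uy + pos(i, 2) * uz;
      py[i] = pos(i, 0) * vx + pos(i, 1) * vy + pos(i, 2) * vz;
    }
    out[d] = raster_union_area(px, py, rr, res);
  }
  return out;
}
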