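// Signed-distance evaluation of the phantom solid over a voxel grid.
// The solid is a union of axis-aligned boxes and capped cylinders given
// in the phantom frame; M maps 0-based voxel indices to that frame.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector sdf_grid(IntegerVector dims, NumericMatrix M,
                       NumericMatrix boxes, NumericMatrix cyls) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nb = boxes.nrow(), nc = cyls.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t pos = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      double bx = M(0, 1) * j + M(0, 2) * k + M(0, 3);
      double by = M(1, 1) * j + M(1, 2) * k + M(1, 3);
      double bz = M(2, 1) * j + M(2, 2) * k + M(2, 3);
      for (int i = 0; i < nx; ++i, ++pos) {
        double x = M(0, 0) * i + bx;
        double y = M(1, 0) * i + by;
        double z = M(2, 0) * i + bz;
        double s = R_PosInf;
        for (int b = 0; b < nb; ++b) {
          double qx = std::fabs(x - boxes(b, 0)) - boxes(b, 3) / 2;
          double qy = std::fabs(y - boxes(b, 1)) - boxes(b, 4) / 2;
          double qz = std::fabs(z - boxes(b, 2)) - boxes(b, 5) / 2;
          double ox = qx > 0 ? qx : 0, oy = qy > 0 ? qy : 0, oz = qz > 0 ? qz : 0;
          double outside = std::sqrt(ox * ox + oy * oy + oz * oz);
          double inside = std::fmax(qx, std::fmax(qy, qz));
          double d = outside + (inside < 0 ? inside : 0);
          if (d < s) s = d;
        }
        for (int c = 0; c < nc; ++c) {
          double wx = x - cyls(c, 0), wy = y - cyls(c, 1), wz = z - cyls(c, 2);
          double sp = wx * cyls(c, 3) + wy * cyls(c, 4) + wz * cyls(c, 5);
          double r2 = wx * wx + wy * wy + wz * wz - sp * sp;
          double dr = (r2 > 0 ? std::sqrt(r2) : 0) - cyls(c, 7);
          double dz2 = std::fabs(sp) - cyls(c, 6);
          double odr = dr > 0 ? dr : 0, odz = dz2 > 0 ? dz2 : 0;
          double d = std::sqrt(odr * odr + odz * odz) +
            std::fmin(std::fmax(dr, dz2), 0.0);
          if (d < s) s = d;
        }
        out[pos] = s;
      }
    }
  }
  return out;
}
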