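// Screw-in-pedicle containment: samples the screw's lateral surface and
// tests it against an elliptic tube. With lateral_only the tube's ends
// are open (only the lateral wall can be breached), which is the
// physical reading for a pedicle: the screw enters at one end and exits
// into the vertebral body at the other.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
bool screw_tube_contained_cpp(NumericVector e, NumericVector d,
                              NumericVector su, NumericVector sv,
                              double L, double r, int naxial, int ncirc,
                              NumericVector pe, NumericVector pd,
                              NumericVector pu, NumericVector pv,
                              double a, double b, double plen,
                              bool lateral_only) {
  const double eps = 1e-9;
  for (int i = 0; i < naxial; ++i) {
    double t = L * i / (naxial - 1);
    double cx = e[0] + t * d[0], cy = e[1] + t * d[1], cz = e[2] + t * d[2];
    for (int j = 0; j < ncirc; ++j) {
      double ph = 2.0 * M_PI * j / ncirc;
      double c = std::cos(ph) * r, s = std::sin(ph) * r;
      double px = cx + c * su[0] + s * sv[0];
      double py = cy + c * su[1] + s * sv[1];
      double pz = cz + c * su[2] + s * sv[2];
      double wx = px - pe[0], wy = py - pe[1], wz = pz - pe[2];
      double ax = wx * pd[0] + wy * pd[1] + wz * pd[2];
      if (ax < -eps || ax > plen + eps) {
        if (lateral_only) continue;
        return false;
      }
      double xu = (wx * pu[0] + wy * pu[1] + wz * pu[2]) / a;
      double yv = (wx * pv[0] + wy * pv[1] + wz * pv[2]) / b;
      if (xu * xu + yv * yv > 1.0 + eps) return false;
    }
  }
  return true;
}
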