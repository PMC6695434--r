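// Feret-diameter scan: axis-aligned extents (padded by per-atom radii)
// under rotations about x then y in fixed angular increments over
// [0, pi/2).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector calliper_scan_cpp(NumericMatrix P, NumericVector r,
                                double step_deg) {
  const int n = P.nrow();
  const double step = step_deg * M_PI / 180.0;
  double best_max = -1.0, best_min = R_PosInf;
  for (double ty = 0.0; ty < M_PI / 2 - 1e-12; ty += step) {
    double cy = std::cos(ty), sy = std::sin(ty);
    for (double tx = 0.0; tx < M_PI / 2 - 1e-12; tx += step) {
      double cx = std::cos(tx), sx = std::sin(tx);
      // R = Ry(ty) %*% Rx(tx), rotated = R p
      double R00 = cy, R01 = sy * sx, R02 = sy * cx;
      double R10 = 0.0, R11 = cx, R12 = -sx;
      double R20 = -sy, R21 = cy * sx, R22 = cy * cx;
      double hi0 = -1e300, lo0 = 1e300, hi1 = -1e300, lo1 = 1e300,
             hi2 = -1e300, lo2 = 1e300;
      for (int i = 0; i < n; ++i) {
        double x = P(i, 0), y = P(i, 1), z = P(i, 2), ri = r[i];
        double u = R00 * x + R01 * y + R02 * z;
        double v = R10 * x + R11 * y + R12 * z;
        double w = R20 * x + R21 * y + R22 * z;
        if (u + ri > hi0) hi0 = u + ri;
        if (u - ri < lo0) lo0 = u - ri;
        if (v + ri > hi1) hi1 = v + ri;
        if (v - ri < lo1) lo1 = v - ri;
        if (w + ri > hi2) hi2 = w + ri;
        if (w - ri < lo2) lo2 = w - ri;
      }
      double e0 = hi0 - lo0, e1 = hi1 - lo1, e2 = hi2 - lo2;
      double emax = std::max(e0, std::max(e1, e2));
      double emin = std::min(e0, std::min(e1, e2));
      if (emax > best_max) best_max = emax;
      if (emin < best_min) best_min = emin;
    }
  }
  return NumericVector::create(best_max, best_min);
}
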