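#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Matched parallel-beam projector pair (pixel-driven, bilinear detector
// weights, optional sub-pixel supersampling). cpp_forward and
// cpp_backproject are exact adjoints of each other for equal arguments,
// which keeps FBP, SIRT and the Radon oracle mutually consistent.
//
// Conventions: slice is n x n, pixel centers at 0-based indices, grid
// center at (n-1)/2; for rotation angle theta the detector coordinate of
// pixel (x, y) is s = (x - c) cos(theta) + (y - c) sin(theta) + axis,
// measured in detector pixels about the (fractional) axis column.

// [[Rcpp::export]]
NumericMatrix cpp_forward(NumericMatrix img, NumericVector anglesRad,
                          double axis, int ndet, int supersample) {
  const int n = img.nrow();
  const int na = anglesRad.size();
  const int ss = supersample < 1 ? 1 : supersample;
  const double c = (n - 1.0) / 2.0;
  const double w = 1.0 / (ss * ss);
  NumericMatrix out(na, ndet);
  for (int ia = 0; ia < na; ++ia) {
    const double co = std::cos(anglesRad[ia]);
    const double si = std::sin(anglesRad[ia]);
    for (int iy = 0; iy < n; ++iy) {
      for (int ix = 0; ix < n; ++ix) {
        const double v = img(iy, ix);
        if (v == 0.0) continue;
        for (int sy = 0; sy < ss; ++sy) {
          const double y = iy - c + (sy + 0.5) / ss - 0.5;
          for (int sx = 0; sx < ss; ++sx) {
            const double x = ix - c + (sx + 0.5) / ss - 0.5;
            const double t = x * co + y * si + axis;
            const int i0 = (int)std::floor(t);
            const double fr = t - i0;
            if (i0 >= 0 && i0 < ndet)
              out(ia, i0) += v * w * (1.0 - fr);
            if (i0 + 1 >= 0 && i0 + 1 < ndet)
              out(ia, i0 + 1) += v * w * fr;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix sino, NumericVector anglesRad,
                              double axis, int n, int supersample) {
  const int na = sino.nrow();
  const int ndet = sino.ncol();
  const int ss = supersample < 1 ? 1 : supersample;
  const double c = (n - 1.0) / 2.0;
  const double w = 1.0 / (ss * ss);
  NumericMatrix out(n, n);
  for (int ia = 0; ia < na; ++ia) {
    const double co = std::cos(anglesRad[ia]);
    const double si = std::sin(anglesRad[ia]);
    for (int iy = 0; iy < n; ++iy) {
      for (int ix = 0; ix < n; ++ix) {
        double acc = 0.0;
        for (int sy = 0; sy < ss; ++sy) {
          const double y = iy - c + (sy + 0.5) / ss - 0.5;
          for (int sx = 0; sx < ss; ++sx) {
            const double x = ix - c + (sx + 0.5) / ss - 0.5;
            const double t = x * co + y * si + axis;
            const int i0 = (int)std::floor(t);
            const double fr = t - i0;
            if (i0 >= 0 && i0 < ndet)
              acc += sino(ia, i0) * (1.0 - fr);
            if (i0 + 1 >= 0 && i0 + 1 < ndet)
              acc += sino(ia, i0 + 1) * fr;
          }
        }
        out(iy, ix) += acc * w;
      }
    }
  }
  return out;
}
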