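#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local thickness disk/sphere sweep. r2[q] is the squared inscribed radius
// (physical units^2) at foreground pixel q (<= 0 on background). Every
// foreground pixel paints its inscribed disk; each covered pixel keeps the
// largest covering squared radius. Coverage uses the same floating-point
// expression for squared distance as the EDT/oracle (axis-ordered sum of
// delta^2 * spacing^2), so the result is bit-identical to the brute-force
// definition. Returns max covering r^2 per pixel (0 where uncovered).
// [[Rcpp::export(name = ".thickness_sweep_cpp")]]
NumericVector thickness_sweep_cpp(NumericVector r2, IntegerVector dim,
                                  NumericVector spacing) {
  int nd = dim.size();
  if (nd != 2 && nd != 3) stop("only 2D and 3D rasters are supported");
  R_xlen_t n = 1;
  for (int a = 0; a < nd; ++a) n *= dim[a];
  if (n != r2.size()) stop("r2 length does not match dim");

  NumericVector out(n);
  double w1 = spacing[0] * spacing[0];
  double w2 = spacing[1] * spacing[1];
  int d1 = dim[0], d2 = dim[1];

  if (nd == 2) {
    for (int x2 = 0; x2 < d2; ++x2) {
      for (int x1 = 0; x1 < d1; ++x1) {
        R_xlen_t q = (R_xlen_t)x2 * d1 + x1;
        double rq2 = r2[q];
        if (rq2 <= 0.0) continue;
        double r = std::sqrt(rq2);
        int h1 = (int)std::floor(r / spacing[0]) + 1;
        int h2 = (int)std::floor(r / spacing[1]) + 1;
        int lo2 = std::max(0, x2 - h2), hi2 = std::min(d2 - 1, x2 + h2);
        int lo1 = std::max(0, x1 - h1), hi1 = std::min(d1 - 1, x1 + h1);
        for (int j2 = lo2; j2 <= hi2; ++j2) {
          double dj2 = (double)(j2 - x2);
          double dd2 = w2 * (dj2 * dj2);
          R_xlen_t col = (R_xlen_t)j2 * d1;
          for (int j1 = lo1; j1 <= hi1; ++j1) {
            double dj1 = (double)(j1 - x1);
            double dd = w1 * (dj1 * dj1) + dd2;
            if (dd <= rq2) {
              R_xlen_t j = col + j1;
              if (rq2 > out[j]) out[j] = rq2;
            }
          }
        }
      }
    }
  } else {
    double w3 = spacing[2] * spacing[2];
    int d3 = dim[2];
    R_xlen_t plane = (R_xlen_t)d1 * d2;
    for (int x3 = 0; x3 < d3; ++x3) {
      for (int x2 = 0; x2 < d2; ++x2) {
        for (int x1 = 0; x1 < d1; ++x1) {
          R_xlen_t q = (R_xlen_t)x3 * plane + (R_xlen_t)x2 * d1 + x1;
          double rq2 = r2[q];
          if (rq2 <= 0.0) continue;
          double r = std::sqrt(rq2);
          int h1 = (int)std::floor(r / spacing[0]) + 1;
          int h2 = (int)std::floor(r / spacing[1]) + 1;
          int h3 = (int)std::floor(r / spacing[2]) + 1;
          int lo3 = std::max(0, x3 - h3), hi3 = std::min(d3 - 1, x3 + h3);
          int lo2 = std::max(0, x2 - h2), hi2 = std::min(d2 - 1, x2 + h2);
          int lo1 = std::max(0, x1 - h1), hi1 = std::min(d1 - 1, x1 + h1);
          // Squared distance is accumulated as ((w1*d1 + w2*d2) + w3*d3),
          // matching the EDT's axis-ordered association exactly.
          for (int j3 = lo3; j3 <= hi3; ++j3) {
            double dj3 = (double)(j3 - x3);
            double dd3 = w3 * (dj3 * dj3);
            for (int j2 = lo2; j2 <= hi2; ++j2) {
              double dj2 = (double)(j2 - x2);
              double dd2 = w2 * (dj2 * dj2);
              R_xlen_t row = (R_xlen_t)j3 * plane + (R_xlen_t)j2 * d1;
              for (int j1 = lo1; j1 <= hi1; ++j1) {
                double dj1 = (double)(j1 - x1);
                double dd = (w1 * (dj1 * dj1) + dd2) + dd3;
                if (dd <= rq2) {
                  R_xlen_t j = row + j1;
                  if (rq2 > out[j]) out[j] = rq2;
                }
              }
            }
          }
        }
      }
    }
  }
  return out;
}
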