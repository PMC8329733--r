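#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zhang-Suen thinning of a 2D binary raster (column-major, dim = c(nr, nc)).
// Produces a 1-pixel-wide 8-connected skeleton; fully deterministic.
// [[Rcpp::export(name = ".thin_cpp")]]
IntegerVector thin_cpp(IntegerVector mask, IntegerVector dim) {
  if (dim.size() != 2) stop("thinning is 2D only");
  int nr = dim[0], nc = dim[1];
  if ((R_xlen_t)nr * nc != mask.size()) stop("mask length does not match dim");

  std::vector<char> img(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) img[i] = mask[i] != 0;

  auto at = [&](int r, int c) -> char {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img[(R_xlen_t)c * nr + r];
  };

  bool changed = true;
  std::vector<R_xlen_t> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!at(r, c)) continue;
          // neighbours P2..P9 clockwise starting north
          char p2 = at(r - 1, c), p3 = at(r - 1, c + 1), p4 = at(r, c + 1),
               p5 = at(r + 1, c + 1), p6 = at(r + 1, c), p7 = at(r + 1, c - 1),
               p8 = at(r, c - 1), p9 = at(r - 1, c - 1);
          int b = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (b < 2 || b > 6) continue;
          int a = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (a != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((R_xlen_t)c * nr + r);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i) img[kill[i]] = 0;
    }
  }

  IntegerVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = img[i];
  return out;
}
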