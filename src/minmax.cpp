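#include <Rcpp.h>
#include <deque>
#include <vector>
using namespace Rcpp;

// Sliding window minimum (or maximum) along one axis of a 2D matrix via the
// monotonic-deque algorithm: O(n) regardless of window size. Used for
// grayscale erosion/dilation with a square structuring element, which makes
// large-radius background estimation (rolling-ball-style top-hat) feasible.
static void slide_lines(const NumericVector& x, NumericVector& out, int d1,
                        int d2, int axis, int half, bool want_min) {
  int len = (axis == 0) ? d1 : d2;
  int nlines = (axis == 0) ? d2 : d1;
  R_xlen_t stride = (axis == 0) ? 1 : d1;
  R_xlen_t jump = (axis == 0) ? d1 : 1;
  std::deque<int> dq;
  for (int l = 0; l < nlines; ++l) {
    R_xlen_t base = (R_xlen_t)l * jump;
    dq.clear();
    // windows are [t - half, t + half], processed with a half-lag
    for (int t = 0; t < len + half; ++t) {
      if (t < len) {
        double v = x[base + (R_xlen_t)t * stride];
        while (!dq.empty()) {
          double back = x[base + (R_xlen_t)dq.back() * stride];
          if (want_min ? (back >= v) : (back <= v)) dq.pop_back();
          else break;
        }
        dq.push_back(t);
      }
      int centre = t - half;
      if (centre >= 0) {
        while (!dq.empty() && dq.front() < centre - half) dq.pop_front();
        out[base + (R_xlen_t)centre * stride] =
            x[base + (R_xlen_t)dq.front() * stride];
      }
    }
  }
}

// [[Rcpp::export(name = ".sliding_extremum_cpp")]]
NumericVector sliding_extremum_cpp(NumericVector x, IntegerVector dim,
                                   int half, bool want_min) {
  if (dim.size() != 2) stop("2D matrices only");
  int d1 = dim[0], d2 = dim[1];
  if ((R_xlen_t)d1 * d2 != x.size()) stop("length does not match dim");
  NumericVector tmp(x.size()), out(x.size());
  slide_lines(x, tmp, d1, d2, 0, half, want_min);
  slide_lines(tmp, out, d1, d2, 1, half, want_min);
  return out;
}
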