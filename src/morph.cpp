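#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Offsets of the full neighbourhood (8-connectivity in 2D, 26 in 3D).
static void full_neighbourhood(int nd, std::vector<std::vector<int> >& offs) {
  offs.clear();
  if (nd == 2) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        if (a || b) offs.push_back({a, b});
  } else {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (a || b || c) offs.push_back({a, b, c});
  }
}

// Axis-aligned neighbourhood (4-connectivity in 2D, 6 in 3D) -- used for the
// background complement when filling holes (standard duality with 8/26 fg).
static void axis_neighbourhood(int nd, std::vector<std::vector<int> >& offs) {
  offs.clear();
  for (int a = 0; a < nd; ++a) {
    std::vector<int> p(nd, 0), m(nd, 0);
    p[a] = 1;
    m[a] = -1;
    offs.push_back(p);
    offs.push_back(m);
  }
}

static inline R_xlen_t lin_index(const std::vector<int>& c,
                                 const IntegerVector& dim) {
  R_xlen_t idx = 0, stride = 1;
  for (int a = 0; a < dim.size(); ++a) {
    idx += (R_xlen_t)c[a] * stride;
    stride *= dim[a];
  }
  return idx;
}

// Connected-component labelling of a binary raster with full (8/26)
// connectivity. Labels are assigned in raster-scan order of each component's
// first pixel, so the result is deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(IntegerVector mask, IntegerVector dim) {
  int nd = dim.size();
  if (nd != 2 && nd != 3) stop("only 2D and 3D rasters are supported");
  R_xlen_t n = 1;
  for (int a = 0; a < nd; ++a) n *= dim[a];
  if (n != mask.size()) stop("mask length does not match dim");

  std::vector<std::vector<int> > offs;
  full_neighbourhood(nd, offs);

  IntegerVector lab(n);
  std::vector<int> coord(nd), nb(nd);
  int next = 0;
  std::queue<R_xlen_t> bfs;

  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (mask[seed] == 0 || lab[seed] != 0) continue;
    ++next;
    lab[seed] = next;
    bfs.push(seed);
    while (!bfs.empty()) {
      R_xlen_t cur = bfs.front();
      bfs.pop();
      R_xlen_t rem = cur;
      for (int a = 0; a < nd; ++a) {
        coord[a] = (int)(rem % dim[a]);
        rem /= dim[a];
      }
      for (size_t o = 0; o < offs.size(); ++o) {
        bool ok = true;
        for (int a = 0; a < nd; ++a) {
          nb[a] = coord[a] + offs[o][a];
          if (nb[a] < 0 || nb[a] >= dim[a]) { ok = false; break; }
        }
        if (!ok) continue;
        R_xlen_t j = lin_index(nb, dim);
        if (mask[j] != 0 && lab[j] == 0) {
          lab[j] = next;
          bfs.push(j);
        }
      }
    }
  }
  return lab;
}

// Fill interior holes: background regions (4/6-connected) not reachable from
// the image border become foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
IntegerVector fill_holes_cpp(IntegerVector mask, IntegerVector dim) {
  int nd = dim.size();
  if (nd != 2 && nd != 3) stop("only 2D and 3D rasters are supported");
  R_xlen_t n = 1;
  for (int a = 0; a < nd; ++a) n *= dim[a];
  if (n != mask.size()) stop("mask length does not match dim");

  std::vector<std::vector<int> > offs;
  axis_neighbourhood(nd, offs);

  std::vector<char> outside(n, 0);
  std::queue<R_xlen_t> bfs;
  std::vector<int> coord(nd), nb(nd);

  // seed from all border background pixels
  for (R_xlen_t i = 0; i < n; ++i) {
    if (mask[i] != 0) continue;
    R_xlen_t rem = i;
    bool border = false;
    for (int a = 0; a < nd; ++a) {
      int c = (int)(rem % dim[a]);
      rem /= dim[a];
      if (c == 0 || c == dim[a] - 1) border = true;
    }
    if (border && !outside[i]) {
      outside[i] = 1;
      bfs.push(i);
    }
  }
  while (!bfs.empty()) {
    R_xlen_t cur = bfs.front();
    bfs.pop();
    R_xlen_t rem = cur;
    for (int a = 0; a < nd; ++a) {
      coord[a] = (int)(rem % dim[a]);
      rem /= dim[a];
    }
    for (size_t o = 0; o < offs.size(); ++o) {
      bool ok = true;
      for (int a = 0; a < nd; ++a) {
        nb[a] = coord[a] + offs[o][a];
        if (nb[a] < 0 || nb[a] >= dim[a]) { ok = false; break; }
      }
      if (!ok) continue;
      R_xlen_t j = lin_index(nb, dim);
      if (mask[j] == 0 && !outside[j]) {
        outside[j] = 1;
        bfs.push(j);
      }
    }
  }
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (mask[i] != 0 || !outside[i]) ? 1 : 0;
  return out;
}
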