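#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Grayscale opening with a ball (non-flat, hemispherical) structuring
// element: erosion by the ball followed by dilation. This is the classical
// rolling-ball background estimator -- the opened image is the surface traced
// by a ball of the given radius rolled under the intensity landscape.
// Out-of-bounds offsets are ignored, which keeps opening <= image and makes
// a constant image an exact fixed point.
// [[Rcpp::export]]
NumericMatrix ball_opening_cpp(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> di, dj;
  std::vector<double> h;
  const double r2 = (double)radius * radius;
  for (int i = -radius; i <= radius; ++i) {
    for (int j = -radius; j <= radius; ++j) {
      double d2 = (double)i * i + (double)j * j;
      if (d2 <= r2) {
        di.push_back(i);
        dj.push_back(j);
        h.push_back(std::sqrt(r2 - d2));
      }
    }
  }
  const int m = (int)di.size();
  NumericMatrix ero(nr, nc), opened(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = R_PosInf;
      for (int k = 0; k < m; ++k) {
        int rr = r + di[k], cc = c + dj[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double t = img(rr, cc) - h[k];
        if (t < v) v = t;
      }
      ero(r, c) = v;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double v = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int rr = r + di[k], cc = c + dj[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        double t = ero(rr, cc) + h[k];
        if (t > v) v = t;
      }
      opened(r, c) = v;
    }
  }
  return opened;
}

// Connected-component labelling of a binary mask with 4- or 8-connectivity,
// two-pass union-find. Labels are assigned in raster-scan order, so the
// result is deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already scanned (column-major): (r-1,c), (r,c-1),
      // and for 8-connectivity (r-1,c-1), (r+1,c-1)
      int neigh[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int nn = (connectivity == 8) ? 4 : 2;
      int cur = 0;
      for (int k = 0; k < nn; ++k) {
        int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (cur == 0) cur = l; else unite(cur, l);
        }
      }
      if (cur == 0) {
        cur = next++;
        parent.push_back(cur);
      }
      lab(r, c) = cur;
    }
  }
  // second pass: compress and renumber consecutively
  std::vector<int> newlab(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find(l);
      if (newlab[root] == 0) newlab[root] = ++out;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
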