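// 8-connected component labelling (flood fill) and bilinear rotation with
// border-replicate sampling. Matrices follow R's (row, col) layout.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cc_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + nr * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          int qj = pj + dj;
          if (qj < 0 || qj >= nc) continue;
          for (int di = -1; di <= 1; ++di) {
            int qi = pi + di;
            if (qi < 0 || qi >= nr || (di == 0 && dj == 0)) continue;
            if (mask(qi, qj) && lab(qi, qj) == 0) {
              lab(qi, qj) = next;
              stack.push_back(qi + nr * qj);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Rotate image content by `angle` degrees (counter-clockwise with row 1 at
// the top) about the centre; out-of-range samples replicate the border.
// [[Rcpp::export]]
NumericMatrix rotate_replicate(NumericMatrix img, double angle) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double th = angle * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cy = (nr - 1) / 2.0, cx = (nc - 1) / 2.0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double dr = i - cy, dc = j - cx;
      double sr = cy + ct * dr - st * dc;
      double sc = cx + st * dr + ct * dc;
      if (sr < 0) sr = 0; else if (sr > nr - 1) sr = nr - 1;
      if (sc < 0) sc = 0; else if (sc > nc - 1) sc = nc - 1;
      int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      int r1 = std::min(r0 + 1, nr - 1), c1 = std::min(c0 + 1, nc - 1);
      double fr = sr - r0, fc = sc - c0;
      out(i, j) = (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
                  fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
    }
  }
  return out;
}
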