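// 8-connected component labeling of a binary matrix (iterative flood
// fill); labels are contiguous from 1 in column-major discovery order.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(IntegerMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        ++next;
        stack.clear();
        stack.push_back(std::make_pair(i, j));
        lab(i, j) = next;
        while (!stack.empty()) {
          const std::pair<int, int> p = stack.back();
          stack.pop_back();
          for (int dj = -1; dj <= 1; ++dj) {
            for (int di = -1; di <= 1; ++di) {
              const int ii = p.first + di, jj = p.second + dj;
              if (ii >= 0 && ii < h && jj >= 0 && jj < w &&
                  mask(ii, jj) != 0 && lab(ii, jj) == 0) {
                lab(ii, jj) = next;
                stack.push_back(std::make_pair(ii, jj));
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
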