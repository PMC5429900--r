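#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labeling of a binary matrix by breadth-first search.
// Components are numbered 1..k in raster-scan order of their first pixel
// (column-major, matching R's storage), so labeling is deterministic.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> queue;
  queue.reserve(256);
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      queue.clear();
      queue.push_back(i + j * nr);
      while (!queue.empty()) {
        int p = queue.back();
        queue.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = pi + di, qj = pj + dj;
            if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
            if (mask(qi, qj) && !lab(qi, qj)) {
              lab(qi, qj) = next;
              queue.push_back(qi + qj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
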