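// 8-connected component labeling of a binary mask by breadth-first search.
// Labels are assigned in raster (column-major) order of each component's
// first-encountered pixel, so output is deterministic.

#include <Rcpp.h>
#include <vector>

// [[Rcpp::export(name = ".ptr_is_nil")]]
bool ptr_is_nil(SEXP p) {
  return TYPEOF(p) != EXTPTRSXP || R_ExternalPtrAddr(p) == nullptr;
}

// [[Rcpp::export(name = ".label_components_8")]]
Rcpp::IntegerMatrix label_components_8(Rcpp::LogicalMatrix mask) {
  int h = mask.nrow(), w = mask.ncol();
  Rcpp::IntegerMatrix lab(h, w);
  std::vector<int> qi, qj;
  int next = 0;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      size_t head = 0;
      while (head < qi.size()) {
        int ci = qi[head], cj = qj[head];
        ++head;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              qi.push_back(ni); qj.push_back(nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
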