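#include <Rcpp.h>
using namespace Rcpp;

// Zhang-Suen binary thinning. Input: 0/1 integer matrix (foreground = 1),
// assumed padded so that no foreground pixel touches the border.
// Returns the one-pixel-wide skeleton as a 0/1 integer matrix.
// [[Rcpp::export(name = ".thin_mask")]]
IntegerMatrix thin_mask(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  std::vector<std::pair<int, int> > del;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int j = 1; j < nc - 1; ++j) {
        for (int i = 1; i < nr - 1; ++i) {
          if (!img(i, j)) continue;
          int p2 = img(i - 1, j),     p3 = img(i - 1, j + 1);
          int p4 = img(i, j + 1),     p5 = img(i + 1, j + 1);
          int p6 = img(i + 1, j),     p7 = img(i + 1, j - 1);
          int p8 = img(i, j - 1),     p9 = img(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < del.size(); ++k)
        img(del[k].first, del[k].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return img;
}
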