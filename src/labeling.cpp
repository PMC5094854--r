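#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-connected component labeling of a logical matrix by breadth-first
// flood fill. Returns an integer matrix with 0 for background and
// 1..n_components for foreground pixels.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + j * nr);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int ci = idx % nr, cj = idx / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              q.push(ni + nj * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Fill interior holes of a logical mask: background is flood-filled
// (4-connectivity) from the matrix border; anything not reached and not
// foreground is a hole and becomes foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix outside(nr, nc);
  std::queue<int> q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; j += (nc > 1 ? nc - 1 : 1)) {
      if (!mask(i, j) && !outside(i, j)) { outside(i, j) = true; q.push(i + j * nr); }
      if (nc == 1) break;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; i += (nr > 1 ? nr - 1 : 1)) {
      if (!mask(i, j) && !outside(i, j)) { outside(i, j) = true; q.push(i + j * nr); }
      if (nr == 1) break;
    }
  }
  const int di[4] = {1, -1, 0, 0}, dj[4] = {0, 0, 1, -1};
  while (!q.empty()) {
    int idx = q.front(); q.pop();
    int ci = idx % nr, cj = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ni = ci + di[k], nj = cj + dj[k];
      if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
      if (!mask(ni, nj) && !outside(ni, nj)) {
        outside(ni, nj) = true;
        q.push(ni + nj * nr);
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !outside(i, j);
  return out;
}

// Count exposed 4-neighbor edges per labeled component (perimeter in edge
// units); index k of the result corresponds to label k.
// [[Rcpp::export(name = ".edge_perimeter")]]
NumericVector edge_perimeter(IntegerMatrix lab, int nlab) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (!l) continue;
      if (i == 0      || lab(i - 1, j) != l) per[l - 1] += 1;
      if (i == nr - 1 || lab(i + 1, j) != l) per[l - 1] += 1;
      if (j == 0      || lab(i, j - 1) != l) per[l - 1] += 1;
      if (j == nc - 1 || lab(i, j + 1) != l) per[l - 1] += 1;
    }
  }
  return per;
}
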