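#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass 8-connected component labeling with union-find.
// Returns an integer matrix; background 0, components numbered 1..n in
// order of first appearance in a row-major raster scan.

static int findRoot(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".labelComponents8")]]
IntegerMatrix labelComponents8(const LogicalMatrix &mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 0;

  // first pass: row-major scan, merge with already-visited 8-neighbours
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int best = 0;
      // neighbours already scanned in row-major order:
      // (i, j-1), (i-1, j-1), (i-1, j), (i-1, j+1)
      const int di[4] = {0, -1, -1, -1};
      const int dj[4] = {-1, -1, 0, 1};
      int roots[4];
      int nRoots = 0;
      for (int k = 0; k < 4; ++k) {
        int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || jj < 0 || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) roots[nRoots++] = findRoot(parent, l);
      }
      for (int k = 0; k < nRoots; ++k)
        if (best == 0 || roots[k] < best) best = roots[k];
      if (best == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = best;
        for (int k = 0; k < nRoots; ++k)
          if (roots[k] != best) parent[roots[k]] = best;
      }
    }
  }

  // relabel roots consecutively in row-major first-appearance order
  std::vector<int> newLab(next + 1, 0);
  int nOut = 0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = findRoot(parent, l);
      if (newLab[r] == 0) newLab[r] = ++nOut;
      lab(i, j) = newLab[r];
    }
  lab.attr("nComponents") = nOut;
  return lab;
}
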