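#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find connected-component labeling of a binary mask.
// connectivity 4 or 8; returns an integer label matrix (0 = background),
// labels in raster-scan discovery order (relabeled deterministically in R).
static int findRoot(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
IntegerMatrix label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int neigh[4]; int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        int m = neigh[0];
        for (int i = 1; i < nn; ++i) m = std::min(m, neigh[i]);
        m = findRoot(parent, m);
        for (int i = 0; i < nn; ++i) {
          int rt = findRoot(parent, neigh[i]);
          if (rt != m) parent[rt] = m;
        }
        lab(r, c) = m;
      }
    }
  }
  // second pass: flatten labels to consecutive ids
  std::vector<int> remap(next + 1, 0);
  int count = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!lab(r, c)) continue;
      int rt = findRoot(parent, lab(r, c));
      if (!remap[rt]) remap[rt] = ++count;
      lab(r, c) = remap[rt];
    }
  return lab;
}
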