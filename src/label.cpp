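#include <Rcpp.h>
using namespace Rcpp;

// Two-pass connected-component labeling with union-find, 4- or
// 8-connectivity. Foreground = non-zero pixels; labels are 1..n in raster
// order of first occurrence, matching a deterministic scan.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(const LogicalMatrix& binary, int connectivity) {
  const int nr = binary.nrow(), nc = binary.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!binary(r, c)) continue;
      int neigh[4];
      int nn = 0;
      if (r > 0 && binary(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && binary(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8) {
        if (r > 0 && c > 0 && binary(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r < nr - 1 && c > 0 && binary(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      if (nn == 0) {
        ++next;
        parent.push_back(next);
        lab(r, c) = next;
      } else {
        int m = neigh[0];
        for (int k = 1; k < nn; ++k) if (neigh[k] < m) m = neigh[k];
        lab(r, c) = m;
        int rm = find_root(parent, m);
        for (int k = 0; k < nn; ++k) {
          int rk = find_root(parent, neigh[k]);
          if (rk != rm) {
            if (rk < rm) std::swap(rk, rm);
            parent[rk] = rm;
          }
        }
      }
    }
  }

  // relabel roots consecutively in order of first appearance
  std::vector<int> newlab(next + 1, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (!l) continue;
      int root = find_root(parent, l);
      if (!newlab[root]) newlab[root] = ++out;
      lab(r, c) = newlab[root];
    }
  return lab;
}
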