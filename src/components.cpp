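#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

//' @noRd
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background sentinel
  int next = 1;

  // first pass, column-major scan; 8-connectivity.
  // visited neighbours of (i,j): (i-1,j), (i-1,j-1), (i,j-1), (i+1,j-1)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int nb[4];
      int k = 0;
      if (i > 0 && mask(i - 1, j)) nb[k++] = lab(i - 1, j);
      if (j > 0) {
        if (i > 0 && mask(i - 1, j - 1)) nb[k++] = lab(i - 1, j - 1);
        if (mask(i, j - 1)) nb[k++] = lab(i, j - 1);
        if (i + 1 < nr && mask(i + 1, j - 1)) nb[k++] = lab(i + 1, j - 1);
      }
      if (k == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        int m = nb[0];
        for (int t = 1; t < k; ++t) if (nb[t] < m) m = nb[t];
        lab(i, j) = m;
        for (int t = 0; t < k; ++t) if (nb[t] != m) uf_union(parent, nb[t], m);
      }
    }
  }

  // second pass: resolve equivalences, relabel contiguously in scan order
  std::vector<int> newlab(next, 0);
  int K = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newlab[r] == 0) newlab[r] = ++K;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
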