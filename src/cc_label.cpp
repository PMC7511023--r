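#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

//' Label connected components of a logical matrix.
//'
//' Two-pass union-find labelling with selectable pixel connectivity.
//' Components are numbered 1..n in column-major first-encounter order;
//' background (FALSE) pixels are 0.
//'
//' @param mask logical matrix
//' @param connectivity 4 or 8
//' @return integer matrix of component labels
//' @keywords internal
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;

  // provisional labels stored 1-based in lab, parent indexed 0-based
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = -1;
      // previously scanned neighbours (column-major: left column, and above)
      if (r > 0 && mask(r - 1, c)) best = lab(r - 1, c) - 1;
      if (c > 0) {
        if (mask(r, c - 1)) {
          int l = lab(r, c - 1) - 1;
          if (best < 0) best = l; else uf_union(parent, best, l);
        }
        if (connectivity == 8) {
          if (r > 0 && mask(r - 1, c - 1)) {
            int l = lab(r - 1, c - 1) - 1;
            if (best < 0) best = l; else uf_union(parent, best, l);
          }
          if (r < nr - 1 && mask(r + 1, c - 1)) {
            int l = lab(r + 1, c - 1) - 1;
            if (best < 0) best = l; else uf_union(parent, best, l);
          }
        }
      }
      if (best < 0) {
        parent.push_back(next);
        best = next++;
      }
      lab(r, c) = best + 1;
    }
  }

  // resolve and renumber in first-encounter (column-major) order
  std::vector<int> newlab(next, 0);
  int n_final = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!lab(r, c)) continue;
      int root = uf_find(parent, lab(r, c) - 1);
      if (newlab[root] == 0) newlab[root] = ++n_final;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
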