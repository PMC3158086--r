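#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Union-find with path compression for two-pass component labeling.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

//' @noRd
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0);  // label 0 = background
  int next = 1;
  // first pass: scan column-major; neighbours already visited under
  // 8-connectivity are (r-1,c-1), (r,c-1), (r+1,c-1), (r-1,c)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int nb[4][2] = {{r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}, {r - 1, c}};
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) best = (best == 0) ? l : std::min(best, l);
      }
      if (best == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < 4; ++k) {
          int rr = nb[k][0], cc = nb[k][1];
          if (rr < 0 || rr >= nr || cc < 0) continue;
          int l = lab(rr, cc);
          if (l > 0 && l != best) uf_union(parent, l, best);
        }
      }
    }
  }
  // second pass: resolve equivalences and renumber 1..K
  std::vector<int> remap(parent.size(), 0);
  int k = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int root = uf_find(parent, (int)i);
    if (remap[root] == 0) remap[root] = ++k;
    remap[i] = remap[root];
  }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) lab(r, c) = remap[lab(r, c)];
  return lab;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher 2004).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

//' @noRd
// [[Rcpp::export(name = ".edt_sq")]]
NumericMatrix edt_sq(const LogicalMatrix& mask) {
  // squared Euclidean distance from each TRUE pixel to the nearest FALSE
  // pixel (pixels as unit lattice points); FALSE pixels get 0
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // transform along rows (within each column)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    f.resize(nr);
    dt1d(f, dd, v, z);
    for (int r = 0; r < nr; ++r) d(r, c) = dd[r];
    f.resize(nmax);
  }
  // then along columns (within each row)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    f.resize(nc);
    dt1d(f, dd, v, z);
    for (int c = 0; c < nc; ++c) d(r, c) = dd[c];
    f.resize(nmax);
  }
  return d;
}
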