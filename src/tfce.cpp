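#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// union-find with path halving
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, std::vector<int>& csize,
                     int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra == rb) return;
  if (csize[ra] < csize[rb]) std::swap(ra, rb);
  parent[rb] = ra;
  csize[ra] += csize[rb];
}

// TFCE for a 1-D (nc == 1 or nr == 1) or 2-D map stored column-major,
// 4-connectivity, one-sided (only positive values enhanced).
// dh <= 0 requests the default step max(map)/100.
static void tfce_core(const double* map, int nr, int nc,
                      double E, double H, double dh, double* out) {
  const int n = nr * nc;
  std::fill(out, out + n, 0.0);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (map[i] > mx) mx = map[i];
  if (mx <= 0.0) return;
  if (dh <= 0.0) dh = mx / 100.0;
  const int nsteps = (int)std::floor(mx / dh + 1e-9);
  std::vector<int> parent(n), csize(n);
  for (int s = 1; s <= nsteps; ++s) {
    const double h = s * dh;
    for (int i = 0; i < n; ++i) { parent[i] = i; csize[i] = 1; }
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        if (map[i] < h) continue;
        if (r + 1 < nr && map[i + 1] >= h) uf_union(parent, csize, i, i + 1);
        if (c + 1 < nc && map[i + nr] >= h) uf_union(parent, csize, i, i + nr);
      }
    }
    const double hH = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i)
      if (map[i] >= h)
        out[i] += std::pow((double)csize[uf_find(parent, i)], E) * hH;
  }
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector map, int nr, int nc,
                       double E, double H, double dh) {
  if (nr * nc != map.size()) stop("dims do not match map length");
  NumericVector out(map.size());
  tfce_core(map.begin(), nr, nc, E, H, dh, out.begin());
  return out;
}

// Sign-flip permutation null of max TFCE(t).
// zmaps: participants x cells; signs: n_perm x participants (+/-1).
// Each permuted t map is TFCE-enhanced with its own max/100 step
// (dh <= 0) or a fixed dh, and the map-wise maximum recorded.
// [[Rcpp::export(name = ".perm_null_max_cpp")]]
NumericVector perm_null_max_cpp(NumericMatrix zmaps, IntegerMatrix signs,
                                int nr, int nc, double E, double H,
                                double dh) {
  const int np = zmaps.nrow(), ncell = zmaps.ncol();
  if (nr * nc != ncell) stop("dims do not match map length");
  if (signs.ncol() != np) stop("signs must have one column per participant");
  const int nperm = signs.nrow();
  std::vector<double> ss(ncell, 0.0);
  for (int j = 0; j < ncell; ++j)
    for (int i = 0; i < np; ++i) ss[j] += zmaps(i, j) * zmaps(i, j);
  std::vector<double> tmap(ncell), enh(ncell);
  NumericVector null_max(nperm);
  const double sqn = std::sqrt((double)np);
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < ncell; ++j) {
      double m = 0.0;
      for (int i = 0; i < np; ++i) m += signs(p, i) * zmaps(i, j);
      m /= np;
      double var = (ss[j] - np * m * m) / (np - 1);
      if (var <= 0.0) {
        tmap[j] = 0.0;  // degenerate cell; continuous data never hits this
      } else {
        tmap[j] = m / (std::sqrt(var) / sqn);
      }
    }
    tfce_core(tmap.data(), nr, nc, E, H, dh, enh.data());
    double mx = 0.0;
    for (int j = 0; j < ncell; ++j) if (enh[j] > mx) mx = enh[j];
    null_max[p] = mx;
  }
  return null_max;
}
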