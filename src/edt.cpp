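// Exact Euclidean distance transform (squared), two-pass 1-D lower-envelope
// algorithm. Inputs are binary site masks on a grid; outputs are exact
// integer squared distances (in cell units) held in doubles, so results are
// bit-identical to a brute-force all-pairs minimum.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static const double EDT_LARGE = 1e18;

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_LARGE;
  z[1] = EDT_LARGE;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_LARGE;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dx = (double)(q - v[k]);
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix site) {
  int nr = site.nrow(), nc = site.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: down each column
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = site(r, c) ? 0.0 : EDT_LARGE;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  // pass 2: along each row
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = out(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}
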