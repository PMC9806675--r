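#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// One-dimensional squared Euclidean distance transform (lower envelope of
// parabolas), applied independently to each column of F. Sample positions are
// 0, s, 2s, ... so anisotropic grids are handled by the per-axis spacing s.
// F holds current squared distances (R_PosInf where no site seen yet).
// [[Rcpp::export(name = ".dt1d_cols")]]
NumericMatrix dt1d_cols(NumericMatrix F, double s) {
  const int n = F.nrow(), m = F.ncol();
  NumericMatrix D(n, m);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> f(n);
  for (int col = 0; col < m; ++col) {
    for (int i = 0; i < n; ++i) f[i] = F(i, col);
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    bool any = std::isfinite(f[0]);
    for (int q = 1; q < n; ++q) {
      if (!std::isfinite(f[q])) continue;
      if (!any) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; any = true; continue; }
      double xq = q * s;
      double sint;
      while (true) {
        double xv = v[k] * s;
        sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
        if (sint <= z[k] && k > 0) { --k; } else break;
      }
      if (sint <= z[k] && k == 0) { v[0] = q; z[0] = -INF; z[1] = INF; }
      else { ++k; v[k] = q; z[k] = sint; z[k + 1] = INF; }
    }
    if (!any) {
      for (int q = 0; q < n; ++q) D(q, col) = INF;
      continue;
    }
    int j = 0;
    for (int q = 0; q < n; ++q) {
      double xq = q * s;
      while (z[j + 1] < xq) ++j;
      double xv = v[j] * s;
      D(q, col) = (xq - xv) * (xq - xv) + f[v[j]];
    }
  }
  return D;
}
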