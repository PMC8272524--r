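#include <Rcpp.h>
using namespace Rcpp;

// Grid double-sum for the empirical Hoeffding phi-square.
//
// Given pseudo-observations u, v (ranks/n, average ranks for ties), evaluates
//   (1/n^2) * sum_{i,j} [ Chat(i/n, j/n) - (i/n)(j/n) ]^2
// where Chat(u0, v0) = (1/n) * #{k : u_k <= u0, v_k <= v0}.
// The caller multiplies by the p = 2 normalization constant h2 = 90.
//
// Chat on the grid is a 2-D cumulative count; with average tie-ranks the
// atoms sit at (ceil(n*u_k), ceil(n*v_k)) up to fp slack.
// [[Rcpp::export(name = ".phi2_grid_cpp")]]
double phi2_grid_cpp(NumericVector u, NumericVector v) {
  const int n = u.size();
  std::vector<double> cnt((size_t)n * n, 0.0);
  for (int k = 0; k < n; ++k) {
    int i = (int)std::ceil(n * u[k] - 1e-9) - 1;
    int j = (int)std::ceil(n * v[k] - 1e-9) - 1;
    if (i < 0) i = 0; if (i >= n) i = n - 1;
    if (j < 0) j = 0; if (j >= n) j = n - 1;
    cnt[(size_t)i * n + j] += 1.0;
  }
  // cumulative over rows then columns -> n * Chat on the grid
  for (int i = 1; i < n; ++i)
    for (int j = 0; j < n; ++j)
      cnt[(size_t)i * n + j] += cnt[(size_t)(i - 1) * n + j];
  for (int i = 0; i < n; ++i)
    for (int j = 1; j < n; ++j)
      cnt[(size_t)i * n + j] += cnt[(size_t)i * n + j - 1];
  const double dn = (double)n;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d = cnt[(size_t)i * n + j] / dn - ((i + 1) / dn) * ((j + 1) / dn);
      acc += d * d;
    }
  }
  return acc / (dn * dn);
}
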