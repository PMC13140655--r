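#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Plug-in transfer entropy (bits) from pre-discretized series.
// xb, yb are 1-based bin indices over the full window of length n; the
// usable triplets are (y[t+lag], y[t], x[t]) for t = 1..n-lag.
static double te_bits(const int* xb, const int* yb, int n, int lag,
                      int nx, int ny,
                      std::vector<double>& c3, std::vector<double>& cyx,
                      std::vector<double>& cyl, std::vector<double>& cy) {
  const int m = n - lag;
  std::fill(c3.begin(), c3.end(), 0.0);
  std::fill(cyx.begin(), cyx.end(), 0.0);
  std::fill(cyl.begin(), cyl.end(), 0.0);
  std::fill(cy.begin(), cy.end(), 0.0);
  for (int t = 0; t < m; ++t) {
    const int x = xb[t] - 1, y = yb[t] - 1, yl = yb[t + lag] - 1;
    c3[(yl * ny + y) * nx + x] += 1.0;
    cyx[y * nx + x] += 1.0;
    cyl[yl * ny + y] += 1.0;
    cy[y] += 1.0;
  }
  double te = 0.0;
  const double invm = 1.0 / m;
  for (int yl = 0; yl < ny; ++yl)
    for (int y = 0; y < ny; ++y) {
      const double nyly = cyl[yl * ny + y];
      if (nyly == 0.0) continue;
      for (int x = 0; x < nx; ++x) {
        const double n3 = c3[(yl * ny + y) * nx + x];
        if (n3 == 0.0) continue;
        te += n3 * invm * std::log2((n3 * cy[y]) / (cyx[y * nx + x] * nyly));
      }
    }
  return te > 0.0 ? te : 0.0;
}

// [[Rcpp::export]]
double te_plugin_c(IntegerVector xb, IntegerVector yb, int lag,
                   int nx, int ny) {
  const int n = xb.size();
  std::vector<double> c3((size_t)nx * ny * ny), cyx((size_t)nx * ny),
      cyl((size_t)ny * ny), cy(ny);
  return te_bits(&xb[0], &yb[0], n, lag, nx, ny, c3, cyx, cyl, cy);
}

// Observed TE plus n_shuffles surrogate TEs, each computed after a uniform
// random permutation (Fisher-Yates driven by R's RNG, so set.seed() in R
// makes results reproducible) of the full source series.
// [[Rcpp::export]]
NumericVector te_null_c(IntegerVector xb, IntegerVector yb, int lag,
                        int nx, int ny, int n_shuffles) {
  const int n = xb.size();
  std::vector<double> c3((size_t)nx * ny * ny), cyx((size_t)nx * ny),
      cyl((size_t)ny * ny), cy(ny);
  NumericVector out(n_shuffles + 1);
  out[0] = te_bits(&xb[0], &yb[0], n, lag, nx, ny, c3, cyx, cyl, cy);
  std::vector<int> perm(n);
  RNGScope scope;
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = 0; i < n; ++i) perm[i] = xb[i];
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    out[s + 1] = te_bits(perm.data(), &yb[0], n, lag, nx, ny,
                         c3, cyx, cyl, cy);
  }
  return out;
}
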