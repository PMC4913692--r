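#include <Rcpp.h>
using namespace Rcpp;

static inline double partial_r(double rxy, double rxz, double ryz) {
  // first-order partial correlation of (x, y) conditioning on z;
  // degenerate conditioning (|r| = 1 within 1e-12) => fully explainable => 0
  if (std::fabs(rxz) >= 1.0 - 1e-12 || std::fabs(ryz) >= 1.0 - 1e-12) return 0.0;
  return (rxy - rxz * ryz) / std::sqrt((1.0 - rxz * rxz) * (1.0 - ryz * ryz));
}

// PCIT trio scan: for every trio (x, y, z) compute the three first-order
// partial correlations, form the local tolerance eps as the mean |partial /
// direct| over the pairs whose direct correlation is nonzero, and flag an
// edge (x, y) as eliminated if |r_xy| <= eps*|r_xz| and |r_xy| <= eps*|r_yz|
// for some z (strict = FALSE switches <= to <). An all-zero trio imposes no
// constraint. Returns the symmetric elimination indicator matrix.
//
// [[Rcpp::export]]
LogicalMatrix pcit_scan(NumericMatrix r, bool strict_ties = true) {
  const int n = r.nrow();
  LogicalMatrix elim(n, n);
  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = r(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = r(x, z), ryz = r(y, z);
        const double pxy = partial_r(rxy, rxz, ryz);
        const double pxz = partial_r(rxz, rxy, ryz);
        const double pyz = partial_r(ryz, rxy, rxz);
        double tol = 0.0;
        int k = 0;
        if (rxy != 0.0) { tol += std::fabs(pxy / rxy); ++k; }
        if (rxz != 0.0) { tol += std::fabs(pxz / rxz); ++k; }
        if (ryz != 0.0) { tol += std::fabs(pyz / ryz); ++k; }
        if (k == 0) continue;
        tol /= k;
        const double axy = std::fabs(rxy), axz = std::fabs(rxz), ayz = std::fabs(ryz);
        bool exy, exz, eyz;
        if (strict_ties) {
          exy = (axy <= tol * axz) && (axy <= tol * ayz);
          exz = (axz <= tol * axy) && (axz <= tol * ayz);
          eyz = (ayz <= tol * axy) && (ayz <= tol * axz);
        } else {
          exy = (axy < tol * axz) && (axy < tol * ayz);
          exz = (axz < tol * axy) && (axz < tol * ayz);
          eyz = (ayz < tol * axy) && (ayz < tol * axz);
        }
        if (exy) { elim(x, y) = true; elim(y, x) = true; }
        if (exz) { elim(x, z) = true; elim(z, x) = true; }
        if (eyz) { elim(y, z) = true; elim(z, y) = true; }
      }
    }
  }
  return elim;
}
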