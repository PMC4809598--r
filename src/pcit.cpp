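#include <Rcpp.h>
using namespace Rcpp;

// First-order partial correlation with a guarded denominator: returns 0
// when either conditioning correlation is (numerically) 1 in absolute
// value, i.e. the partial is undefined.
static inline double partial(double rxy, double rxz, double ryz) {
  double den = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
  if (den < 1e-24) return 0.0;
  return (rxy - rxz * ryz) / std::sqrt(den);
}

// PCIT trio elimination over all ordered trios (x < y < z).
// For each trio, the three first-order partials are computed, the local
// tolerance eps is the mean of |partial/direct| over terms whose direct
// correlation exceeds 1e-12 in absolute value, and an edge is eliminated
// when its |direct| is <= eps times the |direct| of both other edges.
// An edge is significant if no trio eliminates it. Optionally accumulates
// the mean first-order partial per pair (for the "partial" edge
// statistic).
// [[Rcpp::export]]
List pcit_scan_cpp(NumericMatrix R, bool accumulate_partials) {
  const int n = R.nrow();
  const double tiny = 1e-12;
  LogicalMatrix elim(n, n);
  NumericMatrix psum(accumulate_partials ? n : 1,
                     accumulate_partials ? n : 1);

  for (int x = 0; x < n - 2; ++x) {
    for (int y = x + 1; y < n - 1; ++y) {
      const double rxy = R(x, y);
      for (int z = y + 1; z < n; ++z) {
        const double rxz = R(x, z), ryz = R(y, z);
        const double pxy = partial(rxy, rxz, ryz);
        const double pxz = partial(rxz, rxy, ryz);
        const double pyz = partial(ryz, rxy, rxz);

        double s = 0.0; int m = 0;
        if (std::abs(rxy) > tiny) { s += std::abs(pxy / rxy); ++m; }
        if (std::abs(rxz) > tiny) { s += std::abs(pxz / rxz); ++m; }
        if (std::abs(ryz) > tiny) { s += std::abs(pyz / ryz); ++m; }
        if (m > 0) {
          const double eps = s / m;
          const double axy = std::abs(rxy), axz = std::abs(rxz),
                       ayz = std::abs(ryz);
          if (axy <= eps * axz && axy <= eps * ayz) {
            elim(x, y) = elim(y, x) = true;
          }
          if (axz <= eps * axy && axz <= eps * ayz) {
            elim(x, z) = elim(z, x) = true;
          }
          if (ayz <= eps * axy && ayz <= eps * axz) {
            elim(y, z) = elim(z, y) = true;
          }
        }
        if (accumulate_partials) {
          psum(x, y) += pxy; psum(x, z) += pxz; psum(y, z) += pyz;
        }
      }
    }
  }
  if (accumulate_partials && n > 2) {
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        psum(i, j) /= (n - 2);
        psum(j, i) = psum(i, j);
      }
  }
  return List::create(_["eliminated"] = elim, _["mean_partial"] = psum);
}
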