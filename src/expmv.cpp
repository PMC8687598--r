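#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Action of exp(t*A) on v by uniformization, for a generator-type sparse
// matrix A in compressed-column form (slots of a dgCMatrix): nonnegative
// off-diagonals, nonpositive diagonal. rate must be >= max |diag(A)|.
// e^{tA} v = sum_m e^{-rate t} (rate t)^m / m!  (I + A/rate)^m v.
// [[Rcpp::export]]
NumericVector unif_expmv_cpp(IntegerVector Ap, IntegerVector Ai,
                             NumericVector Ax, NumericVector v,
                             double rate, double t, double tol) {
  const int m = v.size();
  NumericVector out(m), u = clone(v), tmp(m);
  if (t == 0.0 || rate == 0.0) return clone(v);
  const double lt = rate * t;
  int mmax = (int)std::max(20.0, R::qpois(tol, lt, 0, 0) + 10.0);
  double logw = -lt; // log weight for term 0
  for (int i = 0; i < m; ++i) out[i] = std::exp(logw) * v[i];
  for (int j = 1; j <= mmax; ++j) {
    // tmp = (A u) / rate, computed column-wise
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int col = 0; col < m; ++col) {
      const double uc = u[col];
      if (uc == 0.0) continue;
      for (int idx = Ap[col]; idx < Ap[col + 1]; ++idx)
        tmp[Ai[idx]] += Ax[idx] * uc;
    }
    for (int i = 0; i < m; ++i) u[i] += tmp[i] / rate;
    logw += std::log(lt) - std::log((double)j);
    if (logw > -745.0) {
      const double w = std::exp(logw);
      for (int i = 0; i < m; ++i) out[i] += w * u[i];
    }
  }
  return out;
}
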