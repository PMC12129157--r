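#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over a flat list of parameter arrays.
// P, M, V are owned exclusively by the training loop (never aliased),
// so updating their memory directly is safe and avoids copying the
// ~15M-parameter state three times per gradient step.
// [[Rcpp::export(name = ".adam_update_inplace")]]
void adam_update_inplace(List P, List G, List M, List V, double t,
                         double lr, double beta1, double beta2, double eps) {
  const double a = lr / (1.0 - std::pow(beta1, t));      // bias-corrected step
  const double s2 = 1.0 / std::sqrt(1.0 - std::pow(beta2, t));
  const double b1c = 1.0 - beta1, b2c = 1.0 - beta2;
  for (R_xlen_t k = 0; k < P.size(); ++k) {
    SEXP ps = P[k], gs = G[k], ms = M[k], vs = V[k];
    double *p = REAL(ps), *g = REAL(gs), *m = REAL(ms), *v = REAL(vs);
    const R_xlen_t n = XLENGTH(ps);
    for (R_xlen_t i = 0; i < n; ++i) {
      const double gi = g[i];
      const double mi = beta1 * m[i] + b1c * gi;
      const double vi = beta2 * v[i] + b2c * gi * gi;
      m[i] = mi;
      v[i] = vi;
      p[i] -= a * mi / (std::sqrt(vi) * s2 + eps);
    }
  }
}
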