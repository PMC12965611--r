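#include <Rcpp.h>
using namespace Rcpp;

// Fused in-place Adam update over the flat parameter vector.
// th, m and v are owned by the optimizer environment and never aliased
// with model parameters, so in-place mutation is safe.
// [[Rcpp::export]]
void adam_update_cpp(NumericVector th, NumericVector m, NumericVector v,
                     NumericVector g, double b1, double b2,
                     double c1, double c2, double lr, double eps) {
  R_xlen_t n = th.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = b1 * m[i] + (1.0 - b1) * gi;
    double vi = b2 * v[i] + (1.0 - b2) * gi * gi;
    m[i] = mi;
    v[i] = vi;
    th[i] -= lr * (mi * c1) / (std::sqrt(vi * c2) + eps);
  }
}
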