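#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-algorithm log-likelihood for an HMM given the matrix of
// per-observation state-dependent densities (n x K), the transition matrix
// (K x K, rows sum to 1) and the initial distribution. Returns -Inf when the
// forward variables degenerate (zero or non-finite scaling constant).
// [[Rcpp::export]]
double forward_loglik_cpp(NumericMatrix dens, NumericMatrix trans,
                          NumericVector delta) {
  int n = dens.nrow(), K = dens.ncol();
  std::vector<double> v(K), w(K);
  double ll = 0.0, c = 0.0;
  for (int k = 0; k < K; k++) { v[k] = delta[k] * dens(0, k); c += v[k]; }
  if (c <= 0.0 || !R_finite(c)) return R_NegInf;
  ll += std::log(c);
  for (int k = 0; k < K; k++) v[k] /= c;
  for (int i = 1; i < n; i++) {
    c = 0.0;
    for (int k = 0; k < K; k++) {
      double s = 0.0;
      for (int j = 0; j < K; j++) s += v[j] * trans(j, k);
      w[k] = s * dens(i, k);
      c += w[k];
    }
    if (c <= 0.0 || !R_finite(c)) return R_NegInf;
    ll += std::log(c);
    for (int k = 0; k < K; k++) v[k] = w[k] / c;
  }
  return ll;
}
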