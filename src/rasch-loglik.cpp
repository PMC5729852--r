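#include <Rcpp.h>
using namespace Rcpp;

// Per-person Bernoulli-logistic log-likelihood under the fixed-discrimination
// item response model: sum_k w_ik * log P(Y_ik | theta_i), with
// log sigma(eta) = -softplus(-eta) evaluated stably. Missing responses carry
// weight 0 and contribute nothing.
// [[Rcpp::export]]
NumericVector rasch_loglik_rows(NumericVector theta, NumericVector a,
                                NumericVector b, IntegerMatrix y,
                                IntegerMatrix w) {
  const int n = theta.size(), K = a.size();
  NumericVector out(n);
  for (int k = 0; k < K; ++k) {
    const double ak = a[k], bk = b[k];
    for (int i = 0; i < n; ++i) {
      if (w(i, k)) {
        const double eta = ak * (theta[i] - bk);
        const double lp1 = -((eta < 0 ? -eta : 0.0) + log1p(exp(-fabs(eta))));
        out[i] += y(i, k) ? lp1 : lp1 - eta;
      }
    }
  }
  return out;
}
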