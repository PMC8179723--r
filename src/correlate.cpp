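// Direct-summation autocorrelation at a set of integer lags.

#include <Rcpp.h>

// [[Rcpp::export(name = ".autocorr_kernel")]]
Rcpp::NumericVector autocorr_kernel(Rcpp::NumericVector f,
                                    Rcpp::IntegerVector klags) {
  const R_xlen_t n = f.size();
  const double* x = f.begin();
  Rcpp::NumericVector out(klags.size());
  for (R_xlen_t j = 0; j < klags.size(); ++j) {
    const R_xlen_t k = klags[j];
    long double acc = 0.0L;
    for (R_xlen_t t = 0; t + k < n; ++t) acc += x[t] * x[t + k];
    out[j] = (double)(acc / (long double)(n - k));
    Rcpp::checkUserInterrupt();
  }
  return out;
}
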