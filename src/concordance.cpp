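// Weighted Harrell-type concordance for case-cohort risk scores.
//
// Comparable pairs: i with an event at t_i versus j still at risk beyond t_i
// (t_j > t_i, or t_j == t_i with j censored). Two events at the same time are
// not comparable. Pair weight w_i * w_j; predictor ties count 1/2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".wconcord_cpp")]]
List wconcord_cpp(const arma::vec& time, const arma::ivec& event,
                  const arma::vec& score, const arma::vec& w) {
  const int n = time.n_elem;
  long double num = 0.0L, den = 0.0L;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    const double ti = time[i], si = score[i], wi = w[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const bool comparable =
        (time[j] > ti) || (time[j] == ti && event[j] == 0);
      if (!comparable) continue;
      const double ww = wi * w[j];
      den += ww;
      if (si > score[j]) num += ww;
      else if (si == score[j]) num += 0.5 * ww;
    }
  }
  return List::create(_["concordance"] = (double)(den > 0 ? num / den : NA_REAL),
                      _["weighted_pairs"] = (double)den);
}
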