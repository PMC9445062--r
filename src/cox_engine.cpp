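// Counting-process Cox partial likelihood evaluator.
//
// Risk-set convention: subject i is at risk at time t iff start_i < t <= stop_i.
// This single convention serves the full-cohort likelihood (start = 0), the
// Prentice pseudo-partial likelihood (non-subcohort cases enter one
// representable unit before their own event time) and delayed entry
// (e.g. excluding early follow-up).
//
// Hot loops use raw column-pointer arithmetic (no Armadillo temporaries):
// association scans and selection traversals evaluate this function tens of
// thousands of times.

#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Evaluate log pseudo-partial likelihood, score and observed information at
// beta, optionally with per-subject score residuals and per-death Schoenfeld
// residuals (Breslow form; identical to Efron when event times are untied).
//
// ties: 0 = Breslow, 1 = Efron.
// [[Rcpp::export(name = ".cox_eval_cpp")]]
List cox_eval_cpp(const arma::vec& start, const arma::vec& stop,
                  const arma::ivec& status, const arma::mat& X,
                  const arma::vec& beta, const int ties,
                  const bool want_resid) {
  const int n = X.n_rows, p = X.n_cols;

  arma::vec eta = X * beta;
  arma::vec eeta(n);
  for (int i = 0; i < n; ++i) {
    double e = eta[i];
    // clamp so that sums of exp(eta) cannot overflow; a line-search
    // candidate this extreme is rejected via the -Inf log-likelihood below
    if (e > 350.0) e = 350.0; else if (e < -350.0) e = -350.0;
    eta[i] = e;
    eeta[i] = std::exp(e);
  }
  arma::mat Xt = X.t(); // p x n: subject i contiguous in column i

  // distinct event times, increasing
  std::vector<double> evt;
  {
    std::vector<double> tmp;
    tmp.reserve(n);
    for (int i = 0; i < n; ++i) if (status[i] == 1) tmp.push_back(stop[i]);
    std::sort(tmp.begin(), tmp.end());
    for (size_t i = 0; i < tmp.size(); ++i)
      if (i == 0 || tmp[i] != tmp[i - 1]) evt.push_back(tmp[i]);
  }
  const int D = (int)evt.size();

  // deaths bucketed per event time
  std::vector< std::vector<int> > deaths(D);
  for (int i = 0; i < n; ++i) {
    if (status[i] == 1) {
      int k = (int)(std::lower_bound(evt.begin(), evt.end(), stop[i]) - evt.begin());
      deaths[k].push_back(i);
    }
  }

  // order indices by stop desc / start desc for monotone risk-set updates
  std::vector<int> ord_stop(n), ord_start(n);
  for (int i = 0; i < n; ++i) { ord_stop[i] = i; ord_start[i] = i; }
  std::sort(ord_stop.begin(), ord_stop.end(),
            [&](int a, int b) { return stop[a] > stop[b]; });
  std::sort(ord_start.begin(), ord_start.end(),
            [&](int a, int b) { return start[a] > start[b]; });

  double loglik = 0.0;
  arma::vec score(p, arma::fill::zeros);
  arma::mat info(p, p, arma::fill::zeros);
  double* scr = score.memptr();

  double S0 = 0.0;
  arma::vec S1(p, arma::fill::zeros);
  arma::mat S2(p, p, arma::fill::zeros);
  double* s1 = S1.memptr();

  // per-event-time summaries (Breslow form) kept for residual passes
  arma::vec S0k(D), dk(D);
  arma::mat xbar(p, D);
  arma::vec xb(p), S1d(p), md(p);
  arma::mat S2d(p, p);

  int ps = 0, pe = 0; // pointers into ord_stop / ord_start
  for (int k = D - 1; k >= 0; --k) {
    const double t = evt[k];
    // additions: stop >= t
    while (ps < n && stop[ord_stop[ps]] >= t) {
      const int i = ord_stop[ps++];
      const double w = eeta[i];
      const double* xi = Xt.colptr(i);
      S0 += w;
      for (int a = 0; a < p; ++a) {
        const double wxa = w * xi[a];
        s1[a] += wxa;
        double* col = S2.colptr(a);
        for (int b = 0; b < p; ++b) col[b] += wxa * xi[b];
      }
    }
    // removals: start >= t (entered too late to be at risk at t)
    while (pe < n && start[ord_start[pe]] >= t) {
      const int i = ord_start[pe++];
      const double w = eeta[i];
      const double* xi = Xt.colptr(i);
      S0 -= w;
      for (int a = 0; a < p; ++a) {
        const double wxa = w * xi[a];
        s1[a] -= wxa;
        double* col = S2.colptr(a);
        for (int b = 0; b < p; ++b) col[b] -= wxa * xi[b];
      }
    }
    // S0 is a running add/subtract sum; at a numerically degenerate beta
    // (cancellation of huge exp(eta) terms) it can lose positivity. Report
    // the point as -Inf so the optimizer's step-halving backs off.
    if (!(S0 > 0.0) || !std::isfinite(S0)) {
      return List::create(_["loglik"] = R_NegInf,
                          _["score"] = NumericVector(p),
                          _["info"] = arma::mat(p, p, arma::fill::zeros),
                          _["n_events"] = 0,
                          _["event_times"] = evt);
    }

    const std::vector<int>& dset = deaths[k];
    const int d = (int)dset.size();
    double S0d = 0.0;
    const bool efron = (ties == 1 && d > 1);
    if (efron) { S1d.zeros(); S2d.zeros(); }
    for (int ii = 0; ii < d; ++ii) {
      const int i = dset[ii];
      loglik += eta[i];
      const double* xi = Xt.colptr(i);
      for (int a = 0; a < p; ++a) scr[a] += xi[a];
      if (efron) {
        const double w = eeta[i];
        S0d += w;
        double* s1dp = S1d.memptr();
        for (int a = 0; a < p; ++a) {
          const double wxa = w * xi[a];
          s1dp[a] += wxa;
          double* col = S2d.colptr(a);
          for (int b = 0; b < p; ++b) col[b] += wxa * xi[b];
        }
      }
    }

    if (efron) {
      const double* s1dp = S1d.memptr();
      double* mdp = md.memptr();
      for (int r = 0; r < d; ++r) {
        const double frac = (double)r / (double)d;
        const double phi = S0 - frac * S0d;
        const double invphi = 1.0 / phi;
        loglik -= std::log(phi);
        for (int a = 0; a < p; ++a) {
          mdp[a] = (s1[a] - frac * s1dp[a]) * invphi;
          scr[a] -= mdp[a];
        }
        for (int a = 0; a < p; ++a) {
          double* colI = info.colptr(a);
          const double* colS2 = S2.colptr(a);
          const double* colS2d = S2d.colptr(a);
          const double ma = mdp[a];
          for (int b = 0; b < p; ++b)
            colI[b] += (colS2[b] - frac * colS2d[b]) * invphi - mdp[b] * ma;
        }
      }
    } else {
      const double invS0 = 1.0 / S0;
      loglik -= d * std::log(S0);
      double* xbp = xb.memptr();
      for (int a = 0; a < p; ++a) {
        xbp[a] = s1[a] * invS0;
        scr[a] -= d * xbp[a];
      }
      for (int a = 0; a < p; ++a) {
        double* colI = info.colptr(a);
        const double* colS2 = S2.colptr(a);
        const double xa = xbp[a];
        for (int b = 0; b < p; ++b)
          colI[b] += d * (colS2[b] * invS0 - xbp[b] * xa);
      }
    }

    S0k[k] = S0;
    dk[k] = d;
    double* xbc = xbar.colptr(k);
    const double invS0 = 1.0 / S0;
    for (int a = 0; a < p; ++a) xbc[a] = s1[a] * invS0;
  }

  int n_events = 0;
  for (int i = 0; i < n; ++i) n_events += (status[i] == 1);
  List out = List::create(_["loglik"] = loglik,
                          _["score"] = NumericVector(score.begin(), score.end()),
                          _["info"] = info,
                          _["n_events"] = n_events,
                          _["event_times"] = evt);

  if (want_resid) {
    // cumulative hazard-increment sums for score residuals (Breslow form)
    arma::vec G0(D);
    arma::mat G1(p, D);
    double acc0 = 0.0;
    arma::vec acc1(p, arma::fill::zeros);
    for (int k = 0; k < D; ++k) {
      const double h = dk[k] / S0k[k];
      acc0 += h;
      const double* xbc = xbar.colptr(k);
      double* g1c = G1.colptr(k);
      for (int a = 0; a < p; ++a) {
        acc1[a] += h * xbc[a];
        g1c[a] = acc1[a];
      }
      G0[k] = acc0;
    }
    arma::mat U(n, p, arma::fill::zeros);
    for (int i = 0; i < n; ++i) {
      // event times in (start_i, stop_i]
      int hi = (int)(std::upper_bound(evt.begin(), evt.end(), stop[i]) - evt.begin());
      int lo = (int)(std::upper_bound(evt.begin(), evt.end(), start[i]) - evt.begin());
      const double* xi = Xt.colptr(i);
      if (hi > 0) {
        const double g0 = G0[hi - 1] - (lo > 0 ? G0[lo - 1] : 0.0);
        const double* g1hi = G1.colptr(hi - 1);
        const double w = eeta[i];
        if (lo > 0) {
          const double* g1lo = G1.colptr(lo - 1);
          for (int a = 0; a < p; ++a)
            U(i, a) = -w * (xi[a] * g0 - (g1hi[a] - g1lo[a]));
        } else {
          for (int a = 0; a < p; ++a)
            U(i, a) = -w * (xi[a] * g0 - g1hi[a]);
        }
      }
      if (status[i] == 1) {
        int k = (int)(std::lower_bound(evt.begin(), evt.end(), stop[i]) - evt.begin());
        const double* xbc = xbar.colptr(k);
        for (int a = 0; a < p; ++a) U(i, a) += xi[a] - xbc[a];
      }
    }
    // Schoenfeld residuals, one row per death, ordered by event time
    int ndeath = 0;
    for (int k = 0; k < D; ++k) ndeath += (int)deaths[k].size();
    arma::mat schoen(ndeath, p);
    arma::vec schoen_t(ndeath);
    int row = 0;
    for (int k = 0; k < D; ++k) {
      const double* xbc = xbar.colptr(k);
      for (size_t ii = 0; ii < deaths[k].size(); ++ii) {
        const int i = deaths[k][ii];
        const double* xi = Xt.colptr(i);
        for (int a = 0; a < p; ++a) schoen(row, a) = xi[a] - xbc[a];
        schoen_t[row] = evt[k];
        ++row;
      }
    }
    out["score_resid"] = U;
    out["schoenfeld"] = schoen;
    out["schoenfeld_time"] = NumericVector(schoen_t.begin(), schoen_t.end());
  }
  return out;
}
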