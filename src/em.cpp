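// Inner loop of weighted EM for a univariate unequal-variance Gaussian
// mixture. Responsibilities are multiplied by per-sample weights; the
// weighted log-likelihood is returned per iteration so callers can
// assert monotonicity. Collapse (vanishing sd or proportion) is
// reported, not handled: the R wrapper owns restarts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_weighted_em(const arma::vec& x, const arma::vec& w,
                     arma::vec lambda, arma::vec mu, arma::vec sigma,
                     double tol, int maxit, double sd_floor) {
  const int n = x.n_elem, k = lambda.n_elem;
  const double n_eff = arma::accu(w);
  arma::mat dens(n, k);
  std::vector<double> trace;
  double lnl = -arma::datum::inf, lnl_prev = -arma::datum::inf;
  bool collapsed = false, converged = false;
  int it = 0;
  const double log2pi = std::log(2.0 * M_PI);

  while (it < maxit) {
    ++it;
    for (int j = 0; j < k; ++j) {
      const double s = sigma(j), lj = std::log(lambda(j));
      const double c = lj - std::log(s) - 0.5 * log2pi;
      for (int i = 0; i < n; ++i) {
        const double z = (x(i) - mu(j)) / s;
        dens(i, j) = std::exp(c - 0.5 * z * z);
      }
    }
    arma::vec tot = arma::sum(dens, 1);
    if (tot.min() <= 0.0 || !tot.is_finite()) { collapsed = true; break; }
    lnl = arma::accu(w % arma::log(tot));
    trace.push_back(lnl);
    dens.each_col() /= tot;   // responsibilities
    dens.each_col() %= w;     // weighted responsibilities
    arma::rowvec mass = arma::sum(dens, 0);
    if (mass.min() <= 0.0) { collapsed = true; break; }
    for (int j = 0; j < k; ++j) {
      lambda(j) = mass(j) / n_eff;
      double mj = arma::dot(dens.col(j), x) / mass(j);
      arma::vec d = x - mj;
      double vj = arma::dot(dens.col(j), d % d) / mass(j);
      mu(j) = mj;
      sigma(j) = std::sqrt(vj);
    }
    if (sigma.min() < sd_floor || lambda.min() < 1e-12) { collapsed = true; break; }
    if (std::isfinite(lnl_prev) && lnl - lnl_prev < tol) { converged = true; break; }
    lnl_prev = lnl;
  }
  return List::create(_["lambda"] = lambda, _["mu"] = mu, _["sigma"] = sigma,
                      _["lnL"] = lnl, _["n_iter"] = it,
                      _["converged"] = converged, _["collapsed"] = collapsed,
                      _["trace"] = wrap(trace));
}
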