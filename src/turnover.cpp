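// Pruning likelihood for the immigration-death (gain-death) model of
// gene-family size evolution on a rooted species tree.
//
// Along a branch of length t with gain rate gamma (per family) and death
// rate delta (per copy), the count transition is the convolution of a
// binomial thinning of the parent count (survival prob e^{-delta t}) with
// an independent Poisson number of gains, mean (gamma/delta)(1 - e^{-delta t}).
// States are truncated at `cap`; leaves hold observed counts.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// (cap+1) x (cap+1) transition matrix for one branch; binomial and
// Poisson pmfs built by stable recurrences (no R API in the hot loop)
static arma::mat branch_matrix(double t, double gamma, double delta, int cap) {
  const int n = cap + 1;
  const double p = std::exp(-delta * t);
  const double m = (gamma / delta) * (1.0 - p);
  // survivors: B(i,k) = dbinom(k; i, p)
  arma::mat B(n, n, arma::fill::zeros);
  if (p >= 1.0) {
    for (int i = 0; i < n; ++i) B(i, i) = 1.0;
  } else if (p <= 0.0) {
    for (int i = 0; i < n; ++i) B(i, 0) = 1.0;
  } else {
    const double odds = p / (1.0 - p);
    for (int i = 0; i < n; ++i) {
      B(i, 0) = std::pow(1.0 - p, i);
      for (int k = 1; k <= i; ++k)
        B(i, k) = B(i, k - 1) * odds * (double)(i - k + 1) / (double)k;
    }
  }
  // gains: g(d) = dpois(d; m); for extreme m every g underflows to 0 and
  // the resulting zero rows propagate to lnL = -Inf, which the optimiser
  // rejects
  arma::vec g(n, arma::fill::zeros);
  if (m <= 0.0) {
    g(0) = 1.0;
  } else {
    g(0) = std::exp(-m);
    for (int d = 1; d < n; ++d) g(d) = g(d - 1) * m / (double)d;
  }
  arma::mat T(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      const int kmax = std::min(i, j);
      for (int k = 0; k <= kmax; ++k) acc += B(i, k) * g(j - k);
      T(i, j) = acc;
    }
  return T;
}

// Per-family log-likelihood by postorder pruning.
//
// edge:   n_edge x 2 (parent, child), 1-based ape node ids, postorder
//         (every child edge precedes the edge above it)
// counts: n_tip x n_fam observed leaf counts; tip node id == row + 1
// root_prior: 0 = stationary Poisson(prior_gamma/prior_delta),
//             1 = uniform over 0..cap, 2 = point mass at zero
// [[Rcpp::export]]
arma::vec cpp_turnover_loglik(const arma::imat& edge,
                              const arma::vec& blen,
                              const arma::vec& gamma_e,
                              const arma::vec& delta_e,
                              const arma::imat& counts,
                              int cap,
                              int root_prior,
                              double prior_gamma,
                              double prior_delta) {
  const int n_edge = edge.n_rows;
  const int n_tip = counts.n_rows;
  const int n_fam = counts.n_cols;
  const int n_state = cap + 1;
  const int n_node = n_tip + n_edge + 1 - n_tip; // tips + internals
  const int n_total = n_tip + (n_edge - n_tip + 1);
  (void)n_node;

  std::vector<arma::mat> L(n_total + 1);
  std::vector<arma::rowvec> logsc(n_total + 1);
  std::vector<bool> seen(n_total + 1, false);

  // leaf partials
  for (int tip = 1; tip <= n_tip; ++tip) {
    arma::mat Lt(n_state, n_fam, arma::fill::zeros);
    for (int f = 0; f < n_fam; ++f) {
      int c = counts(tip - 1, f);
      if (c < 0 || c > cap) stop("leaf count outside 0..cap");
      Lt(c, f) = 1.0;
    }
    L[tip] = Lt;
    logsc[tip] = arma::rowvec(n_fam, arma::fill::zeros);
    seen[tip] = true;
  }

  for (int e = 0; e < n_edge; ++e) {
    const int par = edge(e, 0), chi = edge(e, 1);
    if (!seen[chi]) stop("edge matrix is not in postorder");
    arma::mat T = branch_matrix(blen(e), gamma_e(e), delta_e(e), cap);
    arma::mat msg = T * L[chi];
    arma::rowvec mx = arma::max(msg, 0);
    mx(arma::find(mx <= 0.0)).fill(1.0); // dead column: leave unscaled
    msg.each_row() /= mx;
    if (!seen[par]) {
      L[par] = msg;
      logsc[par] = logsc[chi] + arma::log(mx);
      seen[par] = true;
    } else {
      L[par] %= msg;
      logsc[par] += logsc[chi] + arma::log(mx);
    }
  }

  const int root = n_tip + 1;
  arma::vec prior(n_state);
  if (root_prior == 0) {
    // truncated Poisson prior, normalised in log space so an extreme
    // gamma/delta ratio cannot produce 0/0
    for (int s = 0; s < n_state; ++s)
      prior(s) = R::dpois(s, prior_gamma / prior_delta, 1);
    prior -= prior.max();
    prior = arma::exp(prior);
    prior /= arma::accu(prior);
  } else if (root_prior == 1) {
    prior.fill(1.0 / n_state);
  } else {
    prior.zeros();
    prior(0) = 1.0;
  }

  arma::vec out(n_fam);
  arma::rowvec rootmass = prior.t() * L[root];
  for (int f = 0; f < n_fam; ++f)
    out(f) = std::log(rootmass(f)) + logsc[root](f);
  return out;
}

// Dense transition matrix, exposed for tests and for ancestral
// reconstruction in R.
// [[Rcpp::export]]
arma::mat cpp_branch_matrix(double t, double gamma, double delta, int cap) {
  return branch_matrix(t, gamma, delta, cap);
}
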