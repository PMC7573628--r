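## Weighted univariate Gaussian mixture fitting of Ks age distributions,
## component-count selection by BIC and by sequential parametric-bootstrap
## LRT, and bootstrap confidence intervals around peak means.

#' Restrict Ks samples to the analysis window
#'
#' Keeps values with `lo <= ks <= hi` (both endpoints inclusive); sample
#' weights travel with their values untouched. The window trims both the
#' near-zero pile-up of allelic/recent duplicates and the saturated tail.
#'
#' @param samples Numeric vector of Ks values, or a data.frame with a
#'   `ks` column (e.g. from [build_weighted_distribution()]).
#' @param lo,hi Window endpoints (defaults 0.05 and 5).
#' @return Same shape as the input, filtered.
#' @export
filter_ks <- function(samples, lo = 0.05, hi = 5) {
  if (is.data.frame(samples)) {
    samples[samples$ks >= lo & samples$ks <= hi, , drop = FALSE]
  } else {
    samples[samples >= lo & samples <= hi]
  }
}

gmm_density <- function(x, lambda, mu, sigma) {
  rowSums(vapply(seq_along(lambda),
                 function(k) lambda[k] * stats::dnorm(x, mu[k], sigma[k]),
                 numeric(length(x))))
}

#' Draw from a Gaussian mixture
#' @param n Number of draws.
#' @param lambda,mu,sigma Component proportions, means, SDs.
#' @return Numeric vector of length `n`.
#' @export
rgmm <- function(n, lambda, mu, sigma) {
  z <- sample.int(length(lambda), n, replace = TRUE, prob = lambda)
  stats::rnorm(n, mu[z], sigma[z])
}

quantile_init <- function(x, w, k) {
  qs <- weighted_quantile(x, w, probs = (seq_len(k) - 0.5) / k)
  mu0 <- sum(w * x) / sum(w)
  sd0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  list(lambda = rep(1 / k, k), mu = qs, sigma = rep(max(sd0, 1e-6), k))
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[o][which(cw >= p)[1L]], numeric(1))
}

#' Weighted EM for a univariate unequal-variance Gaussian mixture
#'
#' Responsibilities are multiplied by the sample weights, so a sample of
#' weight `w` counts as `w` observations; with all weights equal to one
#' this is ordinary EM. The weighted log-likelihood is non-decreasing
#' across iterations; convergence is declared when the gain drops below
#' `tol`. A collapsing component (vanishing SD or proportion) triggers a
#' seeded restart from a perturbed initialisation; after `max_restarts`
#' failures the fit is returned flagged unconverged.
#'
#' @param x Numeric samples.
#' @param w Sample weights in `(0, 1]` (default all 1).
#' @param k Number of components (`>= 1`).
#' @param init Optional list `lambda`, `mu`, `sigma`; default
#'   quantile-spaced means with pooled SD and equal proportions.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param maxit Maximum EM iterations.
#' @param max_restarts Maximum collapse-triggered restarts.
#' @param seed Seed for restart perturbations.
#' @return A `gmm_fit` list: `k`, `lambda`, `mu`, `sigma` (sorted by
#'   mean), `lnL`, `BIC`, `n_eff`, `converged`, `n_iter`.
#' @export
em_fit <- function(x, w = NULL, k, init = NULL, tol = 1e-10, maxit = 1e4,
                   max_restarts = 1000, seed = 1) {
  if (k < 1L) stop("k must be >= 1")
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) != length(x)) stop("weights and samples differ in length")
  n_eff <- sum(w)
  if (n_eff < 3 * k) stop(sprintf("effective sample size %.1f < 3k = %d", n_eff, 3 * k))
  base_init <- if (is.null(init)) quantile_init(x, w, k) else init
  sd_floor <- 1e-10 * max(stats::sd(x), .Machine$double.eps)

  run_em <- function(par) {
    res <- cpp_weighted_em(x, w, par$lambda, par$mu, pmax(par$sigma, sd_floor),
                           tol, as.integer(maxit), sd_floor)
    if (isTRUE(res$collapsed)) return(NULL)
    list(lambda = as.numeric(res$lambda), mu = as.numeric(res$mu),
         sigma = as.numeric(res$sigma), lnL = res$lnL, n_iter = res$n_iter,
         converged = isTRUE(res$converged) || res$n_iter < maxit,
         lnL_trace = as.numeric(res$trace))
  }

  set.seed(seed)
  fit <- run_em(base_init)
  restarts <- 0L
  while (is.null(fit) && restarts < max_restarts) {
    restarts <- restarts + 1L
    pert <- base_init
    pert$mu <- pert$mu + stats::rnorm(k, 0, stats::sd(x) / 4)
    pert$sigma <- pert$sigma * stats::runif(k, 0.5, 2)
    fit <- run_em(pert)
  }
  if (is.null(fit)) {
    fit <- list(lambda = base_init$lambda, mu = base_init$mu,
                sigma = base_init$sigma, lnL = -Inf, n_iter = 0L,
                converged = FALSE, lnL_trace = numeric(0))
  }
  o <- order(fit$mu)
  structure(list(k = k, lambda = fit$lambda[o], mu = fit$mu[o],
                 sigma = fit$sigma[o], lnL = fit$lnL,
                 BIC = 2 * fit$lnL - (3 * k - 1) * log(n_eff),
                 n_eff = n_eff, converged = fit$converged,
                 n_iter = fit$n_iter, n_restarts = restarts,
                 lnL_trace = fit$lnL_trace),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture, k = %d (lnL %.3f, BIC %.3f, n_eff %.1f)\n",
              x$k, x$lnL, x$BIC, x$n_eff))
  print(data.frame(proportion = round(x$lambda, 4), mean = round(x$mu, 4),
                   sd = round(x$sigma, 4)), row.names = FALSE)
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits `k = 1..kmax` (each with a quantile-spaced start plus seeded
#' random restarts) and returns the fit maximising
#' `BIC = 2 lnL - (3k - 1) log(n_eff)`. If the effective sample size is
#' too small for `kmax`, the ceiling is lowered with a message.
#'
#' @inheritParams em_fit
#' @param kmax Largest component count considered (default 9).
#' @param n_restarts Random restarts per `k` in addition to the
#'   deterministic quantile start.
#' @return The best `gmm_fit`; the per-`k` BIC table is attached as
#'   attribute `"bic_table"`.
#' @export
select_k_bic <- function(x, w = NULL, kmax = 9, seed = 1, n_restarts = 2,
                         tol = 1e-10, maxit = 1e4) {
  if (is.null(w)) w <- rep(1, length(x))
  n_eff <- sum(w)
  if (n_eff < 3 * kmax) {
    kmax <- max(1L, floor(n_eff / 3))
    message("effective sample size too small; lowering kmax to ", kmax)
  }
  fits <- vector("list", kmax)
  set.seed(seed)
  for (k in seq_len(kmax)) {
    cand <- list(em_fit(x, w, k, seed = seed + k, tol = tol, maxit = maxit))
    for (r in seq_len(n_restarts)) {
      init <- list(lambda = rep(1 / k, k),
                   mu = sample(x, k, prob = w / sum(w)),
                   sigma = rep(stats::sd(x) * stats::runif(1, 0.3, 1.5), k))
      cand[[r + 1L]] <- em_fit(x, w, k, init = init, seed = seed + 97L * k + r,
                               tol = tol, maxit = maxit)
    }
    fits[[k]] <- cand[[which.max(vapply(cand, `[[`, numeric(1), "lnL"))]]
  }
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  best <- fits[[which.max(bic)]]
  attr(best, "bic_table") <- data.frame(k = seq_len(kmax), BIC = bic,
                                        lnL = vapply(fits, `[[`, numeric(1), "lnL"))
  best
}

#' Select the number of components by sequential parametric-bootstrap LRT
#'
#' Starting at `k = 1`: fit `k` and `k + 1` components, compute the
#' observed likelihood-ratio statistic, simulate `B` datasets from the
#' fitted `k`-component model, refit both on each, and take as p-value
#' the fraction of bootstrap statistics at least as large as observed.
#' Testing advances while `p <= alpha` and stops at the first
#' non-significant test (or at `kmax`).
#'
#' @param x Numeric samples (unweighted).
#' @param kmax Largest component count tested (default 9).
#' @param B Bootstrap replicates per test (default 1000).
#' @param alpha Significance level (default 0.01).
#' @param seed Master seed.
#' @return The selected component count (integer); the per-test p-values
#'   are attached as attribute `"p_values"`.
#' @export
select_k_bootstrap <- function(x, kmax = 9, B = 1000, alpha = 0.01, seed = 1) {
  if (B < 1) stop("B must be >= 1")
  n <- length(x)
  pvals <- numeric(0)
  fit_lnl <- function(y, k, seed_k) {
    f0 <- em_fit(y, k = k, seed = seed_k, tol = 1e-8, maxit = 2000)
    f0
  }
  k <- 1L
  while (k < kmax) {
    f_null <- fit_lnl(x, k, seed + 11L * k)
    f_alt <- fit_lnl(x, k + 1L, seed + 11L * k + 1L)
    lrt_obs <- max(0, 2 * (f_alt$lnL - f_null$lnL))
    set.seed(seed + 1000L * k)
    lrt_boot <- vapply(seq_len(B), function(b) {
      y <- rgmm(n, f_null$lambda, f_null$mu, f_null$sigma)
      b0 <- em_fit(y, k = k, seed = b, tol = 1e-8, maxit = 2000)
      b1 <- em_fit(y, k = k + 1L, seed = b, tol = 1e-8, maxit = 2000)
      max(0, 2 * (b1$lnL - b0$lnL))
    }, numeric(1))
    p <- mean(lrt_boot >= lrt_obs)
    pvals <- c(pvals, p)
    if (p > alpha) break
    k <- k + 1L
  }
  attr(k, "p_values") <- pvals
  k
}

#' Bootstrap confidence intervals around mixture peak means
#'
#' Parametric bootstrap: `B` datasets are simulated from the fitted
#' mixture, refitted at the same `k` (initialised at the fitted
#' parameters), components matched across replicates by sorting means,
#' and percentile intervals taken per component. Replicates whose refit
#' fails or collapses are discarded and counted.
#'
#' @param fit A converged `gmm_fit`.
#' @param n Dataset size per replicate (default: round of `fit$n_eff`).
#' @param B Bootstrap replicates (default 500).
#' @param level Confidence level (default 0.95).
#' @param seed Master seed.
#' @return data.frame with one row per component: `mean`, `lo`, `hi`,
#'   `proportion`; number of discarded replicates in attribute
#'   `"n_discarded"`.
#' @export
peak_confidence_intervals <- function(fit, n = NULL, B = 500, level = 0.95,
                                      seed = 1) {
  if (!isTRUE(fit$converged)) stop("need a converged fit")
  if (is.null(n)) n <- max(3L * fit$k, round(fit$n_eff))
  set.seed(seed)
  means <- matrix(NA_real_, B, fit$k)
  init <- list(lambda = fit$lambda, mu = fit$mu, sigma = fit$sigma)
  discarded <- 0L
  for (b in seq_len(B)) {
    y <- rgmm(n, fit$lambda, fit$mu, fit$sigma)
    rf <- tryCatch(em_fit(y, k = fit$k, init = init, seed = b,
                          tol = 1e-8, maxit = 2000),
                   error = function(e) NULL)
    if (is.null(rf) || !rf$converged) { discarded <- discarded + 1L; next }
    means[b, ] <- sort(rf$mu)
  }
  a <- (1 - level) / 2
  ok <- stats::complete.cases(means)
  ci <- apply(means[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  out <- data.frame(mean = fit$mu, lo = pmin(ci[1L, ], fit$mu),
                    hi = pmax(ci[2L, ], fit$mu), proportion = fit$lambda)
  attr(out, "n_discarded") <- sum(!ok)
  out
}
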