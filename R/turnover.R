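#' Gain-death transition probability
#'
#' Probability that a gene family with `i` copies holds `j` copies a time
#' `t` later, under an immigration-death process: gains arrive at rate
#' `gamma` per family (independent of current size), each existing copy
#' dies at rate `delta`. The transition is closed form: survivors are
#' `Binomial(i, e^(-delta t))` and gains are an independent Poisson with
#' mean `(gamma/delta) (1 - e^(-delta t))`.
#'
#' @param i Starting count (non-negative integer).
#' @param j Ending count (non-negative integer, vectorised).
#' @param t Elapsed time (Myr, `>= 0`).
#' @param gamma Gain rate per family per Myr (`>= 0`).
#' @param delta Death rate per gene copy per Myr (`> 0`).
#' @return `P(X(t) = j | X(0) = i)`, same length as `j`.
#' @export
transition_prob <- function(i, j, t, gamma, delta) {
  if (i < 0 || any(j < 0)) stop("counts must be non-negative")
  if (t < 0) stop("time must be non-negative")
  if (gamma < 0) stop("gamma must be >= 0")
  if (delta <= 0) stop("delta must be > 0")
  p <- exp(-delta * t)
  m <- (gamma / delta) * (1 - p)
  vapply(j, function(jj) {
    k <- 0:min(i, jj)
    sum(stats::dbinom(k, i, p) * stats::dpois(jj - k, m))
  }, numeric(1))
}

## ---- tree plumbing -------------------------------------------------------

# postorder edge matrix + per-edge foreground flag; foreground is the
# terminal branch of the named species (the paper's branch-ratio model)
turnover_tree_data <- function(tree, foreground = NULL) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  fg <- rep(FALSE, nrow(tr$edge))
  if (!is.null(foreground)) {
    tip <- match(foreground, tr$tip.label)
    if (is.na(tip)) stop("foreground species not in tree: ", foreground)
    fg <- tr$edge[, 2L] == tip
    if (!any(fg)) stop("no terminal edge found for ", foreground)
  }
  list(edge = tr$edge, blen = tr$edge.length, foreground = fg,
       n_tip = n_tip, tip_labels = tr$tip.label)
}

# counts: matrix families x species (or named vector for one family)
align_counts <- function(counts, tip_labels) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1L,
                     dimnames = list("family", names(counts)))
  }
  if (is.null(colnames(counts))) stop("count table must name its species columns")
  miss <- setdiff(tip_labels, colnames(counts))
  if (length(miss)) stop("species missing from count table: ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(counts), tip_labels)
  if (length(extra)) stop("count table species not in tree: ",
                          paste(extra, collapse = ", "))
  m <- t(counts[, tip_labels, drop = FALSE])  # species x families
  storage.mode(m) <- "integer"
  m
}

root_prior_code <- function(root_prior) {
  match(match.arg(root_prior, c("stationary", "uniform", "zero")),
        c("stationary", "uniform", "zero")) - 1L
}

#' Gene-family log-likelihood on a species tree
#'
#' Felsenstein pruning over gene-count states `0..cap` under the
#' gain-death transition law, with the root count marginalised under a
#' prior (stationary Poisson by default).
#'
#' @param tree Rooted `phylo` with branch lengths in Myr.
#' @param counts Families x species integer matrix (species as column
#'   names), or a named vector for one family.
#' @param gamma,delta Background gain/death rates.
#' @param foreground Optional species name whose terminal branch takes
#'   `gamma_fg`/`delta_fg`.
#' @param gamma_fg,delta_fg Foreground rates (default: background rates).
#' @param cap State-space cap; auto-raised to at least twice the largest
#'   observed count.
#' @param root_prior `"stationary"`, `"uniform"` or `"zero"`.
#' @return Numeric vector of per-family log-likelihoods.
#' @export
family_loglik <- function(tree, counts, gamma, delta,
                          foreground = NULL, gamma_fg = gamma, delta_fg = delta,
                          cap = NULL, root_prior = "stationary") {
  td <- turnover_tree_data(tree, foreground)
  cm <- align_counts(counts, td$tip_labels)
  cap <- effective_cap(cap, max(cm))
  ge <- ifelse(td$foreground, gamma_fg, gamma)
  de <- ifelse(td$foreground, delta_fg, delta)
  lnl <- cpp_turnover_loglik(td$edge, td$blen, ge, de, cm, cap,
                             root_prior_code(root_prior), gamma, delta)
  stats::setNames(as.numeric(lnl), colnames(cm))
}

effective_cap <- function(cap, max_count) {
  floor_cap <- max(2L * max_count, 10L)
  if (is.null(cap)) return(floor_cap)
  max(as.integer(cap), floor_cap)
}

## ---- fitting -------------------------------------------------------------

#' Fit a gain-death turnover model by maximum likelihood
#'
#' Three branch-rate hypotheses: `"global"` (one gain/death pair over the
#' whole tree), `"branch"` (separate rates on the foreground terminal
#' branch), `"free"` (independent rates on every branch). Optimisation is
#' bounded multi-start ML in log-rate space; the best of `n_restarts`
#' starts (drawn log-uniform within bounds, deterministic given `seed`)
#' is returned.
#'
#' @param tree Rooted `phylo`, branch lengths in Myr.
#' @param counts Families x species integer matrix (rates are shared
#'   across the supplied families; pass a single row to fit one family).
#' @param model `"global"`, `"free"` or `"branch"`.
#' @param foreground Species name for the `"branch"` model.
#' @param n_restarts Number of optimiser starts (default 5).
#' @param seed Integer seed controlling the restart draws.
#' @param cap State cap (auto-raised; see [family_loglik()]).
#' @param root_prior Root-count prior.
#' @param rate_bounds Lower/upper bounds on rates, per Myr.
#' @param condition_on_observed Condition each family's likelihood on the
#'   family being observed in at least one species (default `TRUE`).
#'   All-zero families are unobservable in an orthogroup classification
#'   and are dropped; without this correction the fitted gain rate is
#'   biased upward by the truncation.
#' @return A `turnover_fit` list: `model`, `rates` (data.frame per branch
#'   class or edge), `lnL`, `n_params`, `AIC`, `per_family_lnL`,
#'   `converged`, `n_restarts`, `cap`, `foreground`.
#' @export
fit_turnover <- function(tree, counts,
                         model = c("global", "free", "branch"),
                         foreground = NULL, n_restarts = 5, seed = 1,
                         cap = NULL, root_prior = "stationary",
                         rate_bounds = c(1e-8, 10),
                         condition_on_observed = TRUE) {
  model <- match.arg(model)
  if (model == "branch" && is.null(foreground)) {
    stop("the branch model needs a `foreground` species")
  }
  td <- turnover_tree_data(tree, foreground)
  cm <- align_counts(counts, td$tip_labels)
  keep <- colSums(cm) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " families absent from every species dropped as untestable")
    cm <- cm[, keep, drop = FALSE]
  }
  if (ncol(cm) == 0L) stop("no testable families (all counts zero)")
  cap <- effective_cap(cap, max(cm))
  n_edge <- nrow(td$edge)
  prior_code <- root_prior_code(root_prior)

  lb <- log(rate_bounds[1L]); ub <- log(rate_bounds[2L])
  n_par <- switch(model, global = 2L, branch = 4L, free = 2L * n_edge)

  expand_rates <- function(theta) {
    r <- exp(theta)
    if (model == "global") {
      list(ge = rep(r[1L], n_edge), de = rep(r[2L], n_edge),
           pg = r[1L], pd = r[2L])
    } else if (model == "branch") {
      ge <- ifelse(td$foreground, r[3L], r[1L])
      de <- ifelse(td$foreground, r[4L], r[2L])
      list(ge = ge, de = de, pg = r[1L], pd = r[2L])
    } else {
      ge <- r[seq_len(n_edge)]
      de <- r[n_edge + seq_len(n_edge)]
      list(ge = ge, de = de,
           pg = exp(mean(log(ge))), pd = exp(mean(log(de))))
    }
  }

  # the all-zero pseudo-family rides along as one extra column, giving
  # log P(unobserved) for the ascertainment correction in a single pass
  cm_aug <- if (condition_on_observed) cbind(cm, 0L) else cm
  n_fam <- ncol(cm)
  per_family_lnl <- function(ge, de, pg, pd) {
    lnl <- cpp_turnover_loglik(td$edge, td$blen, ge, de, cm_aug, cap,
                               prior_code, pg, pd)
    if (condition_on_observed) {
      lnl <- lnl[seq_len(n_fam)] - log1p(-exp(lnl[n_fam + 1L]))
    }
    lnl
  }

  negll <- function(theta) {
    rr <- expand_rates(theta)
    val <- -sum(per_family_lnl(rr$ge, rr$de, rr$pg, rr$pd))
    if (!is.finite(val)) 1e12 else val
  }

  set.seed(seed)
  starts <- matrix(stats::runif(n_restarts * n_par, lb, ub),
                   nrow = n_restarts)
  run_starts <- function(fn, starts) {
    best <- NULL; any_conv <- FALSE
    for (r in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[r, ], fn, method = "L-BFGS-B",
                     lower = lb, upper = ub,
                     control = list(maxit = 500L)),
        error = function(e) NULL)
      if (is.null(opt)) next
      if (opt$convergence == 0L) any_conv <- TRUE
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (!is.null(best)) best$any_conv <- any_conv
    best
  }
  # models nesting the global one are warm-started from a quick global
  # fit, so extra branch-rate freedom cannot lose likelihood to a poor
  # draw of random starts
  if (model != "global") {
    g_negll <- function(th2) {
      r2 <- exp(th2)
      val <- -sum(per_family_lnl(rep(r2[1L], n_edge), rep(r2[2L], n_edge),
                                 r2[1L], r2[2L]))
      if (!is.finite(val)) 1e12 else val
    }
    gbest <- run_starts(g_negll, matrix(stats::runif(2 * max(2L, n_restarts %/% 2L),
                                                     lb, ub), ncol = 2))
    if (!is.null(gbest)) {
      warm <- if (model == "branch") gbest$par[c(1L, 2L, 1L, 2L)] else
        c(rep(gbest$par[1L], n_edge), rep(gbest$par[2L], n_edge))
      starts <- rbind(warm, starts[-1L, , drop = FALSE])
    }
  }
  best <- run_starts(negll, starts)
  if (is.null(best)) stop("all optimiser restarts failed")
  any_conv <- isTRUE(best$any_conv)

  rr <- expand_rates(best$par)
  r <- exp(best$par)
  rates <- switch(model,
    global = data.frame(class = "global", gamma = r[1L], delta = r[2L]),
    branch = data.frame(class = c("background", "foreground"),
                        gamma = r[c(1L, 3L)], delta = r[c(2L, 4L)]),
    free = data.frame(class = paste0("edge", seq_len(n_edge)),
                      parent = td$edge[, 1L], child = td$edge[, 2L],
                      gamma = rr$ge, delta = rr$de))
  per_fam <- per_family_lnl(rr$ge, rr$de, rr$pg, rr$pd)
  lnL <- sum(per_fam)
  structure(list(
    model = model, rates = rates, lnL = lnL, n_params = n_par,
    AIC = 2 * n_par - 2 * lnL,
    per_family_lnL = stats::setNames(as.numeric(per_fam), colnames(cm)),
    converged = any_conv, n_restarts = n_restarts, seed = seed,
    cap = cap, root_prior = root_prior, foreground = foreground,
    families = colnames(cm)
  ), class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  cat(sprintf("Gain-death turnover fit (%s model)\n", x$model))
  cat(sprintf("  lnL %.4f, %d parameters, AIC %.4f, %d families, cap %d\n",
              x$lnL, x$n_params, x$AIC, length(x$per_family_lnL), x$cap))
  if (x$model != "free") print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Compare turnover fits by AIC evidence ratio
#'
#' The best model is the one with smallest AIC; the evidence ratio
#' `exp((AIC_second - AIC_best)/2)` says how many times better it is than
#' the runner-up. The selection is called significant when the ratio is
#' at least `ratio_cutoff` (2.7, i.e. a delta-AIC of about 2). AIC ties
#' go to the model with fewer parameters.
#'
#' @param fits A list of `turnover_fit` objects for the same data.
#' @param ratio_cutoff Evidence-ratio threshold (default 2.7).
#' @return A list: `best` (fit), `best_model`, `evidence_ratio`,
#'   `significant`, `table` (model/AIC/delta summary).
#' @export
compare_models <- function(fits, ratio_cutoff = 2.7) {
  if (length(fits) < 2L) stop("need at least 2 fits to compare")
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  npar <- vapply(fits, `[[`, numeric(1), "n_params")
  ord <- order(aic, npar)  # ties toward fewer parameters
  ratio <- exp((aic[ord[2L]] - aic[ord[1L]]) / 2)
  list(best = fits[[ord[1L]]],
       best_model = fits[[ord[1L]]]$model,
       evidence_ratio = ratio,
       significant = ratio >= ratio_cutoff,
       table = data.frame(model = vapply(fits, `[[`, character(1), "model"),
                          n_params = npar, AIC = aic,
                          delta_AIC = aic - min(aic))[ord, ])
}

## ---- ancestral reconstruction / classification ---------------------------

# marginal state posterior at one internal node, by inside-outside passes
node_state_posterior <- function(tree, counts_vec, gamma_e, delta_e, cap,
                                 node, root_prior = "stationary",
                                 prior_gamma, prior_delta) {
  td <- turnover_tree_data(tree)
  cm <- align_counts(counts_vec, td$tip_labels)
  n_tip <- td$n_tip
  n_state <- cap + 1L
  n_node <- n_tip + tree$Nnode
  # inside (pruning) partials
  Tm <- lapply(seq_len(nrow(td$edge)), function(e)
    cpp_branch_matrix(td$blen[e], gamma_e[e], delta_e[e], cap))
  L <- matrix(1, n_state, n_node)
  for (tip in seq_len(n_tip)) {
    L[, tip] <- 0
    L[cm[tip, 1L] + 1L, tip] <- 1
  }
  inside_msg <- vector("list", nrow(td$edge))  # message from child up edge e
  for (e in seq_len(nrow(td$edge))) {
    chi <- td$edge[e, 2L]; par <- td$edge[e, 1L]
    inside_msg[[e]] <- Tm[[e]] %*% L[, chi]
    L[, par] <- L[, par] * inside_msg[[e]]
  }
  root <- n_tip + 1L
  prior <- switch(root_prior,
    stationary = {
      p <- stats::dpois(0:cap, prior_gamma / prior_delta); p / sum(p)
    },
    uniform = rep(1 / n_state, n_state),
    zero = c(1, rep(0, cap)))
  # outside pass, preorder = reverse postorder of edges
  U <- matrix(NA_real_, n_state, n_node)
  U[, root] <- prior
  for (e in rev(seq_len(nrow(td$edge)))) {
    chi <- td$edge[e, 2L]; par <- td$edge[e, 1L]
    sib_prod <- L[, par] / inside_msg[[e]]
    sib_prod[!is.finite(sib_prod)] <- 0
    U[, chi] <- crossprod(Tm[[e]], U[, par] * sib_prod)
  }
  post <- U[, node] * L[, node]
  post / sum(post)
}

#' Classify a family as expanded, contracted or stable on the foreground branch
#'
#' Reconstructs the maximum-posterior ancestral gene count at the parent
#' of the foreground terminal branch under the fitted branch-model rates,
#' and compares it with the observed foreground count. A family that has
#' count zero in the foreground species while the reconstruction is
#' positive is additionally flagged `lost_all`.
#'
#' @param fit A `turnover_fit` from the `"branch"` model.
#' @param tree Rooted species tree.
#' @param counts_vec Named count vector for one family (names = species).
#' @return List: `call` in `{expanded, contracted, stable}`,
#'   `lost_all`, `foreground_count`, `reconstructed_parent`.
#' @export
classify_family <- function(fit, tree, counts_vec) {
  if (fit$model != "branch") stop("classification needs a branch-model fit")
  td <- turnover_tree_data(tree, fit$foreground)
  bg <- fit$rates[fit$rates$class == "background", ]
  fg <- fit$rates[fit$rates$class == "foreground", ]
  ge <- ifelse(td$foreground, fg$gamma, bg$gamma)
  de <- ifelse(td$foreground, fg$delta, bg$delta)
  tip <- match(fit$foreground, td$tip_labels)
  parent <- td$edge[td$edge[, 2L] == tip, 1L]
  cap <- effective_cap(fit$cap, max(counts_vec))
  post <- node_state_posterior(tree, counts_vec, ge, de, cap, parent,
                               root_prior = fit$root_prior,
                               prior_gamma = bg$gamma, prior_delta = bg$delta)
  recon <- which.max(post) - 1L
  obs <- unname(counts_vec[fit$foreground])
  call <- if (obs > recon) "expanded" else if (obs < recon) "contracted" else "stable"
  list(call = call,
       lost_all = (obs == 0L && recon > 0L),
       foreground_count = obs,
       reconstructed_parent = recon)
}
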