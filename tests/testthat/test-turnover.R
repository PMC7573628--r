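test_that("transition probabilities match closed-form special cases", {
  expect_equal(transition_prob(0, 0, 3.7, 0, 1), 1)
  expect_equal(transition_prob(1, 0, log(2), 0, 1), 0.5)  # pure-death half-life
  expect_error(transition_prob(1, 1, -1, 0.1, 0.1), "non-negative")
  expect_error(transition_prob(1, 1, 1, 0.1, 0), "delta")
})

test_that("transition law matches the truncated-generator matrix exponential", {
  skip_if_not_installed("Matrix")
  for (rates in list(c(0.3, 0.5), c(2, 1))) {
    for (t in c(0.5, 2)) {
      for (i in c(0, 2, 5)) {
        ours <- transition_prob(i, 0:15, t, rates[1], rates[2])
        oracle <- vapply(0:15, function(j)
          transition_prob_expm(i, j, t, rates[1], rates[2]), numeric(1))
        expect_equal(ours, oracle, tolerance = 1e-10)
      }
    }
  }
  # the spec'd example point
  expect_equal(transition_prob(2, 1, 1, 0.3, 0.5),
               transition_prob_expm(2, 1, 1, 0.3, 0.5), tolerance = 1e-10)
})

test_that("transition distributions normalise and reach the Poisson equilibrium", {
  for (i in c(0, 3, 10)) {
    for (rates in list(c(0.2, 0.4), c(1, 0.5))) {
      for (t in c(0.1, 1, 10)) {
        expect_equal(sum(transition_prob(i, 0:80, t, rates[1], rates[2])), 1,
                     tolerance = 1e-9)
      }
      t_inf <- 500 / rates[2]
      expect_equal(transition_prob(i, 0:30, t_inf, rates[1], rates[2]),
                   dpois(0:30, rates[1] / rates[2]), tolerance = 1e-6)
    }
  }
})

three_leaf_tree <- function() parse_newick(text = "((A:1.2,B:0.7):0.9,C:2.1);")

test_that("pruning log-likelihood equals exhaustive enumeration on 3-leaf trees", {
  tr <- three_leaf_tree()
  cases <- list(
    list(counts = c(A = 1, B = 1, C = 2), gamma = 0.4, delta = 0.6),
    list(counts = c(A = 0, B = 3, C = 1), gamma = 0.8, delta = 0.3),
    list(counts = c(A = 2, B = 2, C = 2), gamma = 0.1, delta = 1.0))
  for (cs in cases) {
    ours <- family_loglik(tr, cs$counts, cs$gamma, cs$delta, cap = 15)
    oracle <- loglik_enum(tr, cs$counts, cs$gamma, cs$delta, cap = 15)
    expect_equal(unname(ours), oracle, tolerance = 1e-8)
  }
})

test_that("all-zero data under a zero-gain model has probability one", {
  tr <- parse_newick(text = "(A:1,B:1);")
  expect_equal(unname(family_loglik(tr, c(A = 0, B = 0), 0, 1,
                                    root_prior = "zero")), 0)
  # stationary Poisson(0/delta) also concentrates at zero
  expect_equal(unname(family_loglik(tr, c(A = 0, B = 0), 0, 1)), 0)
})

test_that("likelihood is stable to cap doubling and leaf order", {
  tr <- species_tree_11()
  cv <- c(Ath = 2, Atr = 0, Fal = 1, Lpu = 3, Mob = 5, Osj = 1, Pah = 0,
          Sbi = 2, Vsu = 1, Vvi = 2, Zma = 1)
  l1 <- family_loglik(tr, cv, 0.01, 0.02, cap = 12)
  l2 <- family_loglik(tr, cv, 0.01, 0.02, cap = 24)
  expect_equal(unname(l1), unname(l2), tolerance = 1e-8)
  l3 <- family_loglik(tr, cv[sample(names(cv))], 0.01, 0.02, cap = 12)
  expect_equal(unname(l1), unname(l3), tolerance = 1e-12)
})

test_that("species mismatches between tree and counts are errors", {
  tr <- parse_newick(text = "(A:1,B:1);")
  expect_error(family_loglik(tr, c(A = 1, X = 1), 0.1, 0.1), "missing")
  expect_error(family_loglik(tr, c(A = 1, B = 1, X = 2), 0.1, 0.1), "not in tree")
})

test_that("global-model ML recovers simulated rates and drops empty families", {
  tr <- species_tree_11()
  sim <- sim_family_counts(tr, 0.004, 0.005, 400, seed = 31)
  expect_warning(fit <- fit_turnover(tr, sim$counts, "global",
                                     n_restarts = 4, seed = 2),
                 "untestable")
  expect_true(fit$converged)
  expect_equal(fit$AIC, 2 * fit$n_params - 2 * fit$lnL)
  expect_lt(abs(fit$rates$gamma - 0.004) / 0.004, 0.35)
  expect_lt(abs(fit$rates$delta - 0.005) / 0.005, 0.35)
  expect_error(suppressWarnings(
    fit_turnover(tr, sim$counts[rowSums(sim$counts) == 0, , drop = FALSE],
                 "global")),
    "no testable")
})

test_that("free and branch models carry the right parameter counts", {
  tr <- three_leaf_tree()
  set.seed(4)
  counts <- matrix(rpois(30, 1.5), ncol = 3,
                   dimnames = list(sprintf("f%d", 1:10), c("A", "B", "C")))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  fg <- fit_turnover(tr, counts, "global", n_restarts = 3, seed = 1)
  fb <- fit_turnover(tr, counts, "branch", foreground = "C",
                     n_restarts = 3, seed = 1)
  ff <- fit_turnover(tr, counts, "free", n_restarts = 2, seed = 1)
  expect_equal(fg$n_params, 2)
  expect_equal(fb$n_params, 4)
  expect_equal(ff$n_params, 2 * nrow(tr$edge))
  # nesting: more parameters can only improve the maximised likelihood,
  # up to optimiser tolerance
  expect_gte(fb$lnL, fg$lnL - 1e-3)
  expect_error(fit_turnover(tr, counts, "branch"), "foreground")
})

test_that("AIC evidence-ratio selection follows the 2.7 rule", {
  fake <- function(aic, np, model) {
    structure(list(model = model, AIC = aic, n_params = np,
                   lnL = (2 * np - aic) / 2), class = "turnover_fit")
  }
  sel <- compare_models(list(fake(100, 2, "global"), fake(102, 4, "branch")))
  expect_equal(sel$evidence_ratio, exp(1))
  expect_true(sel$significant)     # e ~ 2.718 >= 2.7
  sel2 <- compare_models(list(fake(100, 2, "global"), fake(101, 4, "branch")))
  expect_false(sel2$significant)   # e^0.5 ~ 1.649
  sel3 <- compare_models(list(fake(100, 4, "branch"), fake(100, 2, "global")))
  expect_equal(sel3$evidence_ratio, 1)
  expect_equal(sel3$best_model, "global")  # tie broken toward fewer params
})

test_that("family classification reconstructs the foreground ancestor", {
  tr <- species_tree_11()
  base <- c(Ath = 3, Atr = 3, Fal = 3, Lpu = 3, Mob = 3, Osj = 3, Pah = 3,
            Sbi = 3, Vsu = 3, Vvi = 3, Zma = 3)
  expanded <- base; expanded["Mob"] <- 45
  fit <- fit_turnover(tr, expanded, "branch", foreground = "Mob",
                      n_restarts = 3, seed = 1)
  cls <- classify_family(fit, tr, expanded)
  expect_equal(cls$call, "expanded")
  expect_false(cls$lost_all)
  expect_lt(cls$reconstructed_parent, 45)

  lost <- base; lost["Mob"] <- 0
  fit2 <- fit_turnover(tr, lost, "branch", foreground = "Mob",
                       n_restarts = 3, seed = 1)
  cls2 <- classify_family(fit2, tr, lost)
  expect_equal(cls2$call, "contracted")
  expect_true(cls2$lost_all)
  expect_gt(cls2$reconstructed_parent, 0)
})
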