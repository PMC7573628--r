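ks_mat <- function(labs, fill = NA_real_) {
  m <- matrix(fill, length(labs), length(labs), dimnames = list(labs, labs))
  diag(m) <- 0
  m
}

test_that("cross-pair weights are forced by the sum-to-one rule", {
  # cherry: a single pair with weight 1
  tr <- parse_newick(text = "(A:1,B:1);")
  ks <- ks_mat(c("A", "B")); ks["A", "B"] <- ks["B", "A"] <- 0.2
  w <- node_weighted_ks(tr, ks)
  expect_equal(w$ks, 0.2)
  expect_equal(w$weight, 1)

  # ((A,B),C): inner node contributes (0.2, 1); root two half-weight pairs
  tr2 <- parse_newick(text = "((A:1,B:1):1,C:2);")
  ks2 <- ks_mat(c("A", "B", "C"))
  ks2["A", "B"] <- ks2["B", "A"] <- 0.2
  ks2["A", "C"] <- ks2["C", "A"] <- 1.0
  ks2["B", "C"] <- ks2["C", "B"] <- 1.0
  w2 <- node_weighted_ks(tr2, ks2)
  expect_equal(sort(w2$ks), c(0.2, 1.0, 1.0))
  expect_equal(w2$weight[match(0.2, w2$ks)], 1)
  expect_equal(w2$weight[w2$ks == 1.0], c(0.5, 0.5))

  # 2 x 3 node: six cross pairs, each 1/6
  tr3 <- parse_newick(text = "((A:1,B:1):2,((C:1,D:1):0.5,E:1.5):0.5);")
  ks3 <- ks_mat(c("A", "B", "C", "D", "E"), fill = 1)
  diag(ks3) <- 0
  w3 <- node_weighted_ks(tr3, ks3)
  counts <- table(w3$node)
  expect_true(any(counts == 6))
  expect_equal(unique(w3$weight[w3$node == names(counts)[counts == 6]]), 1 / 6)
  # every node's weights sum to exactly one
  expect_equal(as.vector(tapply(w3$weight, w3$node, sum)),
               rep(1, length(counts)))
})

test_that("missing Ks renormalises over the remaining pairs of a node", {
  tr <- parse_newick(text = "((A:1,B:1):1,C:2);")
  ks <- ks_mat(c("A", "B", "C"))
  ks["A", "B"] <- ks["B", "A"] <- 0.2
  ks["A", "C"] <- ks["C", "A"] <- NA   # saturated
  ks["B", "C"] <- ks["C", "B"] <- 1.0
  w <- node_weighted_ks(tr, ks)
  root_rows <- w[w$ks == 1.0, ]
  expect_equal(root_rows$weight, 1)  # renormalised over the single usable pair
  expect_equal(sum(w$weight), 2)
})

test_that("recursive clade splitting matches the brute-force oracle", {
  # forced cases
  tr <- parse_newick(text = "((A:1,B:1):1,C:2);")
  ks_ok <- ks_mat(c("A", "B", "C"), fill = 1); diag(ks_ok) <- 0
  expect_equal(split_by_ks(tr, ks_ok), list(c("A", "B", "C")))

  cherry <- parse_newick(text = "(A:1,B:1);")
  ks_sat <- ks_mat(c("A", "B")); ks_sat["A", "B"] <- ks_sat["B", "A"] <- 6
  split <- split_by_ks(cherry, ks_sat)
  expect_equal(length(split), 2)
  expect_true(all(lengths(split) == 1))
  # a saturated cherry contributes no weighted sample
  wd <- build_weighted_distribution(list(list(tree = cherry, ks = ks_sat,
                                              family_id = "f")))
  expect_equal(nrow(wd), 0)

  # randomised comparison with the independent recursion oracle
  for (seed in 1:10) {
    sim <- sim_family_tree_with_ks(12, sort(runif(11, 0.1, 4)),
                                   noise_sd = 0.4, seed = seed)
    ours <- lapply(split_by_ks(sim$tree, sim$ks), sort)
    oracle <- split_oracle(sim$tree, sim$ks)
    expect_setequal(lapply(ours, paste, collapse = "|"),
                    lapply(oracle, paste, collapse = "|"))
  }
})

test_that("threshold 5 splits exactly at node age 2.5", {
  sim <- sim_family_tree_with_ks(8, c(0.5, 1.0, 1.5, 2.0, 2.2, 2.4, 2.6),
                                 noise_sd = 0, seed = 3)
  clades <- split_by_ks(sim$tree, sim$ks, threshold = 5)
  # the age-2.6 root (Ks 5.2) must split, nothing else does
  expect_equal(length(clades), 2)
})

test_that("total weight equals the number of contributing duplication nodes", {
  set.seed(77)
  fams <- lapply(1:20, function(i) {
    n <- sample(2:9, 1)
    sim <- sim_family_tree_with_ks(n, sort(runif(n - 1, 0.1, 2.2)),
                                   noise_sd = 0.1, seed = 1000 + i)
    list(tree = sim$tree, ks = sim$ks, family_id = paste0("f", i))
  })
  wd <- build_weighted_distribution(fams, threshold = 5)
  n_nodes <- length(unique(wd$node))
  expect_equal(sum(wd$weight), n_nodes, tolerance = 1e-12)
  # a binary family of n leaves can show at most n - 1 duplication nodes
  per_fam_nodes <- tapply(wd$node, wd$family, function(x) length(unique(x)))
  n_leaves <- vapply(fams, function(f) length(f$tree$tip.label), numeric(1))
  names(n_leaves) <- vapply(fams, `[[`, "", "family_id")
  expect_true(all(per_fam_nodes <= n_leaves[names(per_fam_nodes)] - 1))
  # each leaf pair contributes at most one sample
  for (f in fams[1:5]) {
    w <- build_weighted_distribution(list(f))
    expect_lte(nrow(w), choose(length(f$tree$tip.label), 2))
  }
})

test_that("raising the threshold never loses samples", {
  sim <- sim_family_tree_with_ks(10, sort(runif(9, 0.3, 3.4)), noise_sd = 0.3,
                                 seed = 12)
  fam <- list(list(tree = sim$tree, ks = sim$ks, family_id = "f"))
  n_prev <- -1
  for (thr in c(1, 2, 4, 6, 8)) {
    n_now <- nrow(build_weighted_distribution(fam, threshold = thr))
    expect_gte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("families with fewer than two leaves are skipped with a record", {
  cherry <- parse_newick(text = "(A:1,B:1);")
  ks <- ks_mat(c("A", "B")); ks["A", "B"] <- ks["B", "A"] <- 0.5
  wd <- build_weighted_distribution(list(
    list(tree = cherry, ks = ks, family_id = "good"),
    list(tree = NULL, ks = NULL, family_id = "tiny")))
  expect_equal(attr(wd, "skipped"), "tiny")
  expect_equal(wd$family, "good")
})
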