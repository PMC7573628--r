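test_that("generators are pure functions of parameters and seed", {
  tr <- species_tree_11()
  a <- sim_family_counts(tr, 0.002, 0.003, 40, seed = 5)
  b <- sim_family_counts(tr, 0.002, 0.003, 40, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$counts,
                         sim_family_counts(tr, 0.002, 0.003, 40, seed = 6)$counts))
  p1 <- sim_codon_pair(60, 0.3, 2, 0.2, seed = 9)
  p2 <- sim_codon_pair(60, 0.3, 2, 0.2, seed = 9)
  expect_identical(p1, p2)
  g1 <- sim_nupt_genome(20000, 2000, n_insertions = 3, seed = 4)
  g2 <- sim_nupt_genome(20000, 2000, n_insertions = 3, seed = 4)
  expect_identical(g1, g2)
  expect_identical(substream(7, 3), substream(7, 3))
})

test_that("zero gain from an empty root yields empty families", {
  tr <- species_tree_11()
  sim <- sim_family_counts(tr, 0, 0.01, 25, root_prior = "zero", seed = 2)
  expect_true(all(sim$counts == 0))
})

test_that("single-branch simulation matches the analytic transition law", {
  tr <- parse_newick(text = "(A:2,B:0.0001);")  # A carries the 2-Myr branch
  gamma <- 0.8; delta <- 0.6
  sim <- sim_family_counts(tr, gamma, delta, 20000, root_prior = 3, seed = 33)
  counts <- sim$counts[, "A"]
  expected <- transition_prob(3, 0:12, 2, gamma, delta)
  for (j in c(0, 1, 2, 3, 5)) {
    phat <- mean(counts == j)
    se <- sqrt(expected[j + 1] * (1 - expected[j + 1]) / length(counts))
    expect_lt(abs(phat - expected[j + 1]), 3 * se + 1e-12)
  }
})

test_that("long-branch counts reach the Poisson stationary distribution", {
  gamma <- 0.6; delta <- 0.4
  tr <- parse_newick(text = sprintf("(A:%f,B:0.001);", 1000 / delta))
  sim <- sim_family_counts(tr, gamma, delta, 5000, root_prior = 10, seed = 8)
  counts <- sim$counts[, "A"]
  br <- 0:8
  obs <- table(factor(pmin(counts, 8), levels = br))
  expp <- dpois(br, gamma / delta)
  expp[9] <- 1 - sum(expp[1:8])
  chi <- suppressWarnings(chisq.test(as.numeric(obs), p = expp))
  expect_gt(chi$p.value, 0.001)
})

test_that("codon pairs carry the model's own divergence expectation", {
  p0 <- sim_codon_pair(80, 0, 2, 0.3, seed = 3)
  expect_identical(p0$pair[1], p0$pair[2])

  # omega = kappa = 1: synonymous flux fraction equals site fraction
  cu_pi <- NULL
  dec <- plastburst:::ds_decomposition(1, 1, f3x4_freqs(p0$pair))
  expect_equal(dec$rho_S, dec$f_S, tolerance = 1e-12)

  kappa <- 2; omega <- 0.2; t <- 0.8; n <- 600
  sim <- sim_codon_pair(n, t, kappa, omega, seed = 44)
  cu <- plastburst:::codon_universe()
  pi <- setNames(rep(1 / cu$n, cu$n), cu$codons)
  gen <- gy_generator(kappa, omega, pi)
  P <- plastburst:::gy_transition_matrix(gen$Q, pi, t / 2)
  p_same <- sum(pi * rowSums(P^2))
  cc <- plastburst:::codon_columns(sim$pair)
  obs_diff <- mean(cc$c1 != cc$c2)
  se <- sqrt(p_same * (1 - p_same) / n)
  expect_lt(abs(obs_diff - (1 - p_same)), 3 * se + 0.01)
})

test_that("mixture draws respect the window and planted proportions", {
  lam <- c(0.15, 0.55, 0.30); mu <- c(0.17, 1.62, 2.53); sg <- c(0.05, 0.3, 0.3)
  sim <- sim_ks_mixture(lam, mu, sg, 2000, seed = 10)
  expect_true(all(sim$samples >= 0.05 & sim$samples <= 5))
  assigned <- apply(abs(outer(sim$samples, mu, "-")), 1, which.min)
  props <- tabulate(assigned, 3) / 2000
  expect_true(all(abs(props - lam) < 0.04))
  expect_gt(sim$truth$truth$acceptance_rate, 0.8)
  # degenerate component pins all mass at its mean
  one <- sim_ks_mixture(1, 2, 1e-6, 100, seed = 3)
  expect_equal(mean(one$samples), 2, tolerance = 1e-6)
  # a window that excludes a component lowers acceptance accordingly
  cut <- sim_ks_mixture(c(0.5, 0.5), c(0.2, 10), c(0.05, 0.05), 500,
                        window = c(0.05, 5), seed = 6)
  expect_lt(cut$truth$truth$acceptance_rate, 0.7)
})

test_that("noise-free duplication trees give clock-consistent Ks matrices", {
  sim <- sim_family_tree_with_ks(7, c(0.2, 0.5, 0.9, 1.4, 1.8, 2.2),
                                 noise_sd = 0, seed = 14)
  d <- ape::cophenetic.phylo(sim$tree)
  labs <- rownames(sim$ks)
  expect_equal(sim$ks[labs, labs], d[labs, labs], tolerance = 1e-6)
})

test_that("planted plastid fractions are recoverable from the truth BED", {
  sim <- sim_nupt_genome(150000, 20000, target_bp = 7000, divergence = 0,
                         seed = 22)
  bed <- sim$truth$truth$bed
  expect_equal(sum(bed$end - bed$start), sim$truth$truth$planted_bp)
  expect_equal(sim$truth$truth$planted_bp, 7000)
  # with zero divergence each planted interval is recovered at full identity
  hits <- toy_local_align(sim$plastid, sim$nuclear)
  for (i in seq_len(nrow(bed))) {
    over <- hits[hits$sstart <= bed$end[i] & hits$send >= bed$start[i] + 1, ]
    expect_gte(nrow(over), 1)
    expect_true(any(over$pct_identity == 100))
  }
  f <- tempfile(fileext = ".bed")
  write_truth_bed(sim$truth, f)
  reread <- read.delim(f, header = FALSE)
  expect_equal(nrow(reread), nrow(bed))
})
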