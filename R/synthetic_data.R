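## Seeded generators producing inputs with the statistical structure each
## analysis stage assumes, together with machine-readable ground truth,
## so the whole pipeline is exercised without external genomes.
##
## Every generator is a pure function of (parameters, seed): one master
## seed is split deterministically into substreams with `substream()`, so
## stages can be regenerated independently and byte-identically.

#' Derive a deterministic substream seed from a master seed
#'
#' Stage seeds are `(master * 1000003 + stage index) mod 2^31 - 1`, which
#' keeps every derived seed a valid 32-bit integer and makes substreams
#' reproducible from the (master seed, stage) pair alone.
#'
#' @param master Integer master seed.
#' @param stage Small integer stage index.
#' @return An integer seed.
#' @export
substream <- function(master, stage) {
  as.integer((as.numeric(master) * 1000003 + stage) %% (2^31 - 1))
}

truth_record <- function(generator, seed, params, truth) {
  list(generator = generator, seed = seed, params = params, truth = truth)
}

#' Simulate gene-family counts under the gain-death process on a tree
#'
#' The root count is drawn from the prior, then evolved down every
#' branch under the exact transition law of [transition_prob()]:
#' binomial survival with probability `exp(-delta t)` plus Poisson gains
#' with mean `(gamma/delta)(1 - exp(-delta t))`.
#'
#' @param tree Rooted `phylo`, branch lengths in Myr.
#' @param gamma,delta Background gain/death rates (per Myr).
#' @param n_families Number of families to simulate.
#' @param foreground Optional species whose terminal branch uses
#'   `gamma_fg`/`delta_fg`.
#' @param gamma_fg,delta_fg Foreground rates.
#' @param root_prior `"stationary"` (Poisson gamma/delta), `"zero"`, or
#'   a fixed non-negative integer root count.
#' @param seed Integer seed.
#' @return List: `counts` (families x species integer matrix), `truth`
#'   (a truth record carrying the rates and the simulated root and
#'   internal-node states).
#' @export
sim_family_counts <- function(tree, gamma, delta, n_families,
                              foreground = NULL, gamma_fg = gamma,
                              delta_fg = delta, root_prior = "stationary",
                              seed = 1) {
  if (n_families < 1) stop("n_families must be >= 1")
  td <- turnover_tree_data(tree, foreground)
  set.seed(seed)
  root_count <- if (identical(root_prior, "stationary")) {
    stats::rpois(n_families, gamma / delta)
  } else if (identical(root_prior, "zero")) {
    rep(0L, n_families)
  } else {
    rep(as.integer(root_prior), n_families)
  }
  n_node <- td$n_tip + tree$Nnode
  states <- matrix(NA_integer_, n_node, n_families)
  states[td$n_tip + 1L, ] <- root_count
  # preorder = reverse postorder: parents are filled before children
  for (e in rev(seq_len(nrow(td$edge)))) {
    par <- td$edge[e, 1L]; chi <- td$edge[e, 2L]
    g <- if (td$foreground[e]) gamma_fg else gamma
    d <- if (td$foreground[e]) delta_fg else delta
    p <- exp(-d * td$blen[e])
    m <- (g / d) * (1 - p)
    parent_counts <- states[par, ]
    states[chi, ] <- stats::rbinom(n_families, parent_counts, p) +
      stats::rpois(n_families, m)
  }
  counts <- t(states[seq_len(td$n_tip), , drop = FALSE])
  colnames(counts) <- td$tip_labels
  rownames(counts) <- sprintf("fam%05d", seq_len(n_families))
  storage.mode(counts) <- "integer"
  list(counts = counts,
       truth = truth_record("sim_family_counts", seed,
                            list(gamma = gamma, delta = delta,
                                 gamma_fg = gamma_fg, delta_fg = delta_fg,
                                 foreground = foreground,
                                 root_prior = root_prior),
                            list(root_counts = root_count,
                                 node_states = states)))
}

#' Simulate an aligned codon pair under the GY model
#'
#' An ancestor is drawn from the stationary codon frequencies and two
#' descendants evolved independently for `t/2` along the scaled GY
#' generator, giving total divergence `t` expected substitutions per
#' codon between the pair. The true `dS` implied by the generator's
#' synonymous flux decomposition (the same convention the estimator
#' uses) is returned alongside.
#'
#' @param n_codons Number of codons.
#' @param t Total pairwise divergence (expected substitutions/codon).
#' @param kappa,omega GY parameters.
#' @param pi Codon frequencies (default uniform over the 61 sense
#'   codons).
#' @param seed Integer seed.
#' @return List: `pair` (two aligned sequences), `truth` (with `dS`,
#'   `dN` implied by `(t, kappa, omega, pi)`).
#' @export
sim_codon_pair <- function(n_codons, t, kappa, omega, pi = NULL, seed = 1) {
  cu <- codon_universe()
  if (is.null(pi)) pi <- stats::setNames(rep(1 / cu$n, cu$n), cu$codons)
  gen <- gy_generator(kappa, omega, pi)
  set.seed(seed)
  anc <- sample.int(cu$n, n_codons, replace = TRUE, prob = pi)
  if (t > 0) {
    P <- gy_transition_matrix(gen$Q, pi, t / 2)
    P <- P / rowSums(P)
    d1 <- vapply(anc, function(i) sample.int(cu$n, 1L, prob = P[i, ]), integer(1))
    d2 <- vapply(anc, function(i) sample.int(cu$n, 1L, prob = P[i, ]), integer(1))
  } else {
    d1 <- anc; d2 <- anc
  }
  dec <- ds_decomposition(kappa, omega, pi)
  pair <- c(paste(cu$codons[d1], collapse = ""),
            paste(cu$codons[d2], collapse = ""))
  list(pair = pair,
       truth = truth_record("sim_codon_pair", seed,
                            list(n_codons = n_codons, t = t, kappa = kappa,
                                 omega = omega),
                            list(dS = t * dec$rho_S / (3 * dec$f_S),
                                 dN = t * (1 - dec$rho_S) / (3 * (1 - dec$f_S)),
                                 ancestor = cu$codons[anc])))
}

#' Divergence time that yields a target true dS
#'
#' Inverts the flux decomposition `dS = t rho_S / (3 f_S)` for `t`.
#'
#' @param dS Target synonymous divergence.
#' @param kappa,omega,pi GY parameters (see [sim_codon_pair()]).
#' @return Total divergence `t` in expected substitutions per codon.
#' @export
t_for_ds <- function(dS, kappa, omega, pi = NULL) {
  cu <- codon_universe()
  if (is.null(pi)) pi <- stats::setNames(rep(1 / cu$n, cu$n), cu$codons)
  dec <- ds_decomposition(kappa, omega, pi)
  dS * 3 * dec$f_S / dec$rho_S
}

#' Simulate Ks samples from a Gaussian mixture restricted to a window
#'
#' Draws from the mixture and rejects values outside `[window[1],
#' window[2]]` until `n` samples are accepted.
#'
#' @param lambda,mu,sigma Component proportions, means, SDs.
#' @param n Number of accepted samples.
#' @param window Acceptance window (default `c(0.05, 5)`).
#' @param seed Integer seed.
#' @return List: `samples`, `component` (true component of each sample),
#'   `truth` (parameters and acceptance rate).
#' @export
sim_ks_mixture <- function(lambda, mu, sigma, n, window = c(0.05, 5), seed = 1) {
  set.seed(seed)
  samples <- numeric(0); comp <- integer(0); drawn <- 0L; accepted <- 0L
  while (length(samples) < n) {
    chunk <- max(1000L, 2L * (n - length(samples)))
    z <- sample.int(length(lambda), chunk, replace = TRUE, prob = lambda)
    x <- stats::rnorm(chunk, mu[z], sigma[z])
    drawn <- drawn + chunk
    keep <- x >= window[1L] & x <= window[2L]
    accepted <- accepted + sum(keep)
    samples <- c(samples, x[keep]); comp <- c(comp, z[keep])
  }
  samples <- samples[seq_len(n)]; comp <- comp[seq_len(n)]
  list(samples = samples, component = comp,
       truth = truth_record("sim_ks_mixture", seed,
                            list(lambda = lambda, mu = mu, sigma = sigma,
                                 n = n, window = window),
                            list(acceptance_rate = accepted / drawn)))
}

#' Simulate a duplication tree with a noisy pairwise Ks matrix
#'
#' A random coalescent-style binary topology whose internal nodes take
#' the supplied ages (sorted ascending, joined in age order). Pairwise
#' Ks between two leaves is twice the age of their spanning node plus
#' Gaussian noise, floored at zero — the molecular-clock expectation a
#' duplication-age analysis assumes.
#'
#' @param n_leaves Number of genes.
#' @param node_ages Numeric vector of `n_leaves - 1` node ages (Ks/2
#'   units).
#' @param noise_sd SD of the Gaussian noise added to each pairwise Ks.
#' @param seed Integer seed.
#' @return List: `tree` (rooted binary `phylo`), `ks` (symmetric
#'   matrix), `truth` (node ages and per-node leaf partitions).
#' @export
sim_family_tree_with_ks <- function(n_leaves, node_ages, noise_sd = 0,
                                    seed = 1) {
  if (length(node_ages) != n_leaves - 1L) {
    stop("need exactly n_leaves - 1 node ages")
  }
  set.seed(seed)
  ages <- sort(node_ages)
  labs <- sprintf("g%02d", seq_len(n_leaves))
  # each active lineage is a (newick fragment, height, leaf set) triple
  act <- lapply(seq_len(n_leaves),
                function(i) list(nwk = labs[i], h = 0, leaves = labs[i]))
  node_truth <- list()
  for (k in seq_len(n_leaves - 1L)) {
    pick <- sample.int(length(act), 2L)
    a <- act[[pick[1L]]]; b <- act[[pick[2L]]]
    h <- ages[k]
    merged <- list(
      nwk = sprintf("(%s:%.10f,%s:%.10f)", a$nwk, h - a$h, b$nwk, h - b$h),
      h = h, leaves = c(a$leaves, b$leaves))
    node_truth[[k]] <- list(age = h, left = a$leaves, right = b$leaves)
    act <- c(act[-pick], list(merged))
  }
  tree <- parse_newick(text = paste0(act[[1L]]$nwk, ";"))
  ks <- matrix(NA_real_, n_leaves, n_leaves, dimnames = list(labs, labs))
  diag(ks) <- 0
  for (nd in node_truth) {
    for (x in nd$left) for (y in nd$right) {
      val <- max(0, 2 * nd$age + stats::rnorm(1, 0, noise_sd))
      ks[x, y] <- val; ks[y, x] <- val
    }
  }
  list(tree = tree, ks = ks,
       truth = truth_record("sim_family_tree_with_ks", seed,
                            list(n_leaves = n_leaves, node_ages = ages,
                                 noise_sd = noise_sd),
                            list(nodes = node_truth)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, divergence) {
  if (divergence <= 0) return(seq)
  v <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(v)) < divergence)
  if (length(hit)) {
    v[hit] <- vapply(v[hit],
                     function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                     character(1))
  }
  paste(v, collapse = "")
}

#' Simulate a nuclear genome with planted plastid-DNA insertions
#'
#' A random plastid sequence and a random nuclear background; insertions
#' copy random plastid intervals, mutate them at the given divergence,
#' optionally reverse-complement them, and overwrite non-overlapping
#' nuclear positions (so the genome size stays fixed). Insertion sizes
#' are lognormal — a right-skewed unimodal size distribution — clipped
#' to `[min_size, plastid_bp]`.
#'
#' @param genome_bp Nuclear genome size.
#' @param plastid_bp Plastid genome size.
#' @param n_insertions Number of insertions (ignored when `target_bp`
#'   is given).
#' @param target_bp If set, insertions are drawn until the planted total
#'   reaches this many bp (the last one truncated to land exactly).
#' @param size_meanlog,size_sdlog Lognormal size parameters (defaults
#'   `log(200)` and 1.2).
#' @param min_size Smallest insertion (default 50 bp).
#' @param divergence Per-base substitution probability applied to each
#'   insertion (default 0.05).
#' @param seed Integer seed.
#' @return List: `nuclear`, `plastid` (sequences), `truth` with a BED
#'   data.frame (`chrom`, `start`, `end`, 0-based half-open) of planted
#'   intervals plus per-insertion plastid origin, strand and divergence.
#' @export
sim_nupt_genome <- function(genome_bp, plastid_bp, n_insertions = 0,
                            target_bp = NULL, size_meanlog = log(200),
                            size_sdlog = 1.2, min_size = 50,
                            divergence = 0.05, seed = 1) {
  set.seed(seed)
  plastid <- random_dna(plastid_bp)
  nuclear <- strsplit(random_dna(genome_bp), "")[[1L]]
  occupied <- matrix(numeric(0), ncol = 2)  # 0-based half-open
  bed <- list()
  planted <- 0L
  i <- 0L
  repeat {
    if (is.null(target_bp)) {
      if (i >= n_insertions) break
    } else if (planted >= target_bp) break
    i <- i + 1L
    size <- round(stats::rlnorm(1, size_meanlog, size_sdlog))
    size <- min(max(size, min_size), plastid_bp)
    if (!is.null(target_bp)) size <- min(size, target_bp - planted)  # truncate last
    if (size < 1) break
    # non-overlapping placement by rejection
    pos <- NA
    for (try in 1:200) {
      cand <- sample.int(genome_bp - size + 1L, 1L) - 1L  # 0-based start
      if (nrow(occupied) == 0L ||
          all(cand + size <= occupied[, 1L] | cand >= occupied[, 2L])) {
        pos <- cand; break
      }
    }
    if (is.na(pos)) next  # genome too crowded; skip this insertion
    src <- sample.int(plastid_bp - size + 1L, 1L)
    frag <- substr(plastid, src, src + size - 1L)
    frag <- mutate_dna(frag, divergence)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") frag <- revcomp(frag)
    nuclear[(pos + 1L):(pos + size)] <- strsplit(frag, "")[[1L]]
    occupied <- rbind(occupied, c(pos, pos + size))
    bed[[length(bed) + 1L]] <- data.frame(
      chrom = "nuclear", start = pos, end = pos + size,
      plastid_start = src - 1L, plastid_end = src - 1L + size,
      strand = strand, stringsAsFactors = FALSE)
    planted <- planted + size
  }
  bed <- if (length(bed)) do.call(rbind, bed) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               plastid_start = integer(), plastid_end = integer(),
               strand = character(), stringsAsFactors = FALSE)
  list(nuclear = paste(nuclear, collapse = ""), plastid = plastid,
       truth = truth_record("sim_nupt_genome", seed,
                            list(genome_bp = genome_bp,
                                 plastid_bp = plastid_bp,
                                 n_insertions = n_insertions,
                                 target_bp = target_bp,
                                 size_meanlog = size_meanlog,
                                 size_sdlog = size_sdlog,
                                 divergence = divergence),
                            list(bed = bed, planted_bp = planted,
                                 planted_fraction = planted / genome_bp)))
}

#' Write planted-insertion truth intervals as BED
#' @param truth Truth record from [sim_nupt_genome()].
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  bed <- truth$truth$bed
  utils::write.table(bed[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
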