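# Independent oracles used across the suite. Each one recomputes a
# quantity by a different route than the package (matrix exponential,
# exhaustive enumeration, direct tallies), so agreement is evidence and
# not circularity.

# Immigration-death transition probability via the matrix exponential of
# the truncated birth-death generator (state cap `cap`).
transition_prob_expm <- function(i, j, t, gamma, delta, cap = 60) {
  Q <- matrix(0, cap + 1, cap + 1)
  for (s in 0:(cap - 1)) Q[s + 1, s + 2] <- gamma
  for (s in 1:cap) Q[s + 1, s] <- s * delta
  diag(Q) <- -rowSums(Q)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * t)))
  P[i + 1, j + 1]
}

# family log-likelihood by exhaustive enumeration over all internal-node
# state assignments (only feasible for tiny trees / caps)
loglik_enum <- function(tree, counts_vec, gamma, delta, cap,
                        root_prior = "stationary") {
  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  internals <- (n_tip + 1):(n_tip + tr$Nnode)
  prior <- switch(root_prior,
    stationary = { p <- dpois(0:cap, gamma / delta); p / sum(p) },
    uniform = rep(1 / (cap + 1), cap + 1),
    zero = c(1, rep(0, cap)))
  states <- rep(list(0:cap), length(internals))
  grid <- do.call(expand.grid, states)
  total <- 0
  tipc <- counts_vec[tr$tip.label]
  for (g in seq_len(nrow(grid))) {
    assign <- as.integer(grid[g, ])
    state_of <- function(node) {
      if (node <= n_tip) tipc[node] else assign[match(node, internals)]
    }
    pr <- prior[state_of(n_tip + 1L) + 1L]
    for (e in seq_len(nrow(tr$edge))) {
      pr <- pr * transition_prob(state_of(tr$edge[e, 1L]),
                                 state_of(tr$edge[e, 2L]),
                                 tr$edge.length[e], gamma, delta)
      if (pr == 0) break
    }
    total <- total + pr
  }
  unname(log(total))
}

# ---- NG86 oracle: independent single-file reimplementation ---------------
# Same stated conventions (stop mutations excluded from site counting;
# pathway averaging skipping stop-crossing paths; Jukes-Cantor), written
# from scratch with a different structure (explicit translation table,
# permutation enumeration via recursion on index vectors).

ng86_oracle <- function(seq1, seq2) {
  code <- Biostrings::GENETIC_CODE
  translate1 <- function(codon) unname(code[codon])
  split_codons <- function(s) {
    starts <- seq(1, nchar(s), by = 3)
    substring(s, starts, starts + 2)
  }
  c1 <- split_codons(toupper(seq1)); c2 <- split_codons(toupper(seq2))
  valid_codon <- function(x) !is.na(code[x]) && code[x] != "*" &&
    !grepl("[^ACGT]", x)
  use <- mapply(function(a, b) valid_codon(a) && valid_codon(b), c1, c2)
  c1 <- c1[use]; c2 <- c2[use]

  syn_sites <- function(codon) {
    letters_ <- strsplit(codon, "")[[1]]
    aa <- code[codon]
    total <- 0
    for (pos in 1:3) {
      ns <- 0; nv <- 0
      for (nt in c("A", "C", "G", "T")) {
        if (nt == letters_[pos]) next
        mut <- letters_; mut[pos] <- nt
        mc <- paste(mut, collapse = "")
        if (code[mc] == "*") next
        nv <- nv + 1
        if (code[mc] == aa) ns <- ns + 1
      }
      if (nv > 0) total <- total + ns / nv
    }
    total
  }

  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    res <- list()
    for (i in seq_along(v)) {
      for (tail in perms_of(v[-i])) res[[length(res) + 1]] <- c(v[i], tail)
    }
    res
  }

  pair_diffs <- function(a, b) {
    la <- strsplit(a, "")[[1]]; lb <- strsplit(b, "")[[1]]
    dpos <- which(la != lb)
    if (!length(dpos)) return(c(0, 0))
    all_paths <- perms_of(dpos)
    recs <- matrix(NA_real_, 0, 2)
    recs_stop <- matrix(NA_real_, 0, 2)
    for (path in all_paths) {
      cur <- la; s <- 0; n <- 0; hits_stop <- FALSE
      for (pos in path) {
        before <- paste(cur, collapse = "")
        cur[pos] <- lb[pos]
        after <- paste(cur, collapse = "")
        aa1 <- code[before]; aa2 <- code[after]
        if (aa1 == "*" || aa2 == "*") hits_stop <- TRUE
        if (aa1 == aa2 && aa1 != "*") s <- s + 1 else n <- n + 1
      }
      if (hits_stop) recs_stop <- rbind(recs_stop, c(s, n))
      else recs <- rbind(recs, c(s, n))
    }
    if (nrow(recs) > 0) colMeans(recs) else colMeans(recs_stop)
  }

  S <- (sum(vapply(c1, syn_sites, 0)) + sum(vapply(c2, syn_sites, 0))) / 2
  N <- 3 * length(c1) - S
  dd <- t(mapply(pair_diffs, c1, c2))
  Sd <- sum(dd[, 1]); Nd <- sum(dd[, 2])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# ---- recursive clade-splitting oracle ------------------------------------
# Re-checks every pair at every level using phangorn descendant lists.

split_oracle <- function(tree, ks, threshold = 5) {
  tree <- resolve_polytomies(tree)
  n_tip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, type = "tips")
  kids_of <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  all_ok <- function(labs) {
    if (length(labs) < 2) return(TRUE)
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i < j) {
        v <- ks[labs[i], labs[j]]
        if (is.na(v) || v > threshold) return(FALSE)
      }
    }
    TRUE
  }
  out <- list()
  walk <- function(node) {
    labs <- tree$tip.label[desc[[node]]]
    if (all_ok(labs)) out[[length(out) + 1]] <<- sort(labs)
    else for (ch in kids_of(node)) walk(ch)
  }
  walk(n_tip + 1L)
  out
}

# ---- Fisher two-sided enumeration oracle ----------------------------------

fisher_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  if (n == 0) return(1)
  r1 <- a + b; c1 <- a + c
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- dhyper(xs, c1, n - c1, r1)
  pobs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# quick deterministic random-tree helper
random_gene_tree <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, tip.label = sprintf("g%02d", 1:n_leaves))
  tr
}
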