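## Pairwise synonymous-substitution (Ks) estimation from in-frame codon
## alignments: ML under a GY-type codon model with F3x4 frequencies, and
## the NG86 counting estimator as a fast cross-check.

.pb_env <- new.env(parent = emptyenv())

# Sense-codon universe under the universal genetic code, with the
# single-nucleotide neighbour structure the GY generator is built on.
codon_universe <- function() {
  if (!is.null(.pb_env$cu)) return(.pb_env$cu)
  nt <- c("A", "C", "G", "T")
  grid <- expand.grid(p3 = nt, p2 = nt, p1 = nt, stringsAsFactors = FALSE)
  codons <- paste0(grid$p1, grid$p2, grid$p3)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  sense <- codons[aa != "*"]
  sense_aa <- aa[aa != "*"]
  n <- length(sense)
  idx <- stats::setNames(seq_len(n), sense)
  is_transition <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
  pos <- integer(0)
  for (i in seq_len(n)) {
    ci <- strsplit(sense[i], "")[[1L]]
    for (p in 1:3) {
      for (b in setdiff(nt, ci[p])) {
        cj <- ci; cj[p] <- b
        cjs <- paste(cj, collapse = "")
        j <- idx[cjs]
        if (is.na(j)) next  # change to a stop codon: rate zero
        ii <- c(ii, i); jj <- c(jj, unname(j))
        ts <- c(ts, is_transition(ci[p], b))
        syn <- c(syn, sense_aa[i] == sense_aa[unname(j)])
        pos <- c(pos, p)
      }
    }
  }
  .pb_env$cu <- list(nt = nt, codons = sense, aa = sense_aa, n = n, idx = idx,
                     nbr_i = ii, nbr_j = jj, nbr_ts = ts, nbr_syn = syn,
                     nbr_pos = pos)
  .pb_env$cu
}

# split an aligned pair into codon columns; keep columns where both
# codons are pure ACGT sense codons (gap/ambiguity/stop columns dropped)
codon_columns <- function(pair) {
  if (length(pair) != 2L) stop("need exactly two aligned sequences")
  len <- unique(nchar(pair))
  if (length(len) != 1L) stop("sequences differ in length")
  if (len %% 3L != 0L) stop("alignment length not a multiple of 3")
  cu <- codon_universe()
  starts <- seq(1L, len, by = 3L)
  c1 <- substring(toupper(pair[1L]), starts, starts + 2L)
  c2 <- substring(toupper(pair[2L]), starts, starts + 2L)
  keep <- c1 %in% cu$codons & c2 %in% cu$codons
  list(c1 = c1[keep], c2 = c2[keep], n_used = sum(keep), n_total = length(starts))
}

#' F3x4 equilibrium codon frequencies from an aligned pair
#'
#' Position-specific nucleotide frequencies (tallied over both sequences
#' in the retained codon columns) are multiplied per codon, stop codons
#' removed, and the result renormalised over the 61 sense codons. If the
#' composition is degenerate enough that some sense codon gets frequency
#' zero, a flat pseudocount of `0.5/61` is added to every codon before
#' renormalisation, keeping the generator irreducible.
#'
#' @param pair Character vector of two aligned in-frame sequences.
#' @return Named numeric vector of 61 sense-codon frequencies (sum 1).
#' @export
f3x4_freqs <- function(pair) {
  cc <- codon_columns(pair)
  if (cc$n_used < 1L) stop("no comparable codon columns")
  cu <- codon_universe()
  f <- matrix(0, 3, 4, dimnames = list(NULL, cu$nt))
  for (p in 1:3) {
    obs <- c(substr(cc$c1, p, p), substr(cc$c2, p, p))
    tab <- table(factor(obs, levels = cu$nt))
    if (sum(tab) == 0L) stop("no observed nucleotides at codon position ", p)
    f[p, ] <- as.numeric(tab) / sum(tab)
  }
  m <- matrix(unlist(strsplit(cu$codons, "")), nrow = 3)
  pi <- f[1L, m[1L, ]] * f[2L, m[2L, ]] * f[3L, m[3L, ]]
  if (any(pi == 0)) pi <- pi + 0.5 / cu$n
  pi <- pi / sum(pi)
  stats::setNames(pi, cu$codons)
}

#' GY codon-substitution generator
#'
#' Rate matrix over the 61 sense codons: single-nucleotide changes get
#' rate `pi_j`, times `kappa` for transitions, times `omega` for
#' nonsynonymous changes; multi-nucleotide changes have rate zero. The
#' matrix is scaled so that unit time corresponds to one expected
#' substitution per codon.
#'
#' @param kappa Transition/transversion rate ratio (`> 0`).
#' @param omega dN/dS ratio (`>= 0`).
#' @param pi 61-vector of codon frequencies.
#' @return List: `Q` (scaled generator), `rho_S` (synonymous fraction of
#'   the substitution flux), `scale` (pre-scaling flux).
#' @export
gy_generator <- function(kappa, omega, pi) {
  cu <- codon_universe()
  if (length(pi) != cu$n) stop("pi must have length ", cu$n)
  rate <- pi[cu$nbr_j] * ifelse(cu$nbr_ts, kappa, 1) *
    ifelse(cu$nbr_syn, 1, omega)
  Q <- matrix(0, cu$n, cu$n, dimnames = list(cu$codons, cu$codons))
  Q[cbind(cu$nbr_i, cu$nbr_j)] <- rate
  diag(Q) <- -rowSums(Q)
  flux <- pi[cu$nbr_i] * rate
  total <- sum(flux)
  rho_S <- sum(flux[cu$nbr_syn]) / total
  list(Q = Q / total, rho_S = rho_S, scale = total)
}

# Synonymous flux/site decomposition used to convert t into dS and dN:
# rho_S is the synonymous fraction of flux under (kappa, omega); the
# synonymous site fraction f_S is the same quantity with omega fixed at 1
# (mutational opportunity). dS = t * rho_S / (3 f_S), dN analogous.
ds_decomposition <- function(kappa, omega, pi) {
  rho_S <- gy_generator(kappa, omega, pi)$rho_S
  f_S <- gy_generator(kappa, 1, pi)$rho_S
  list(rho_S = rho_S, f_S = f_S)
}

# transition probability matrix exp(Q t) via eigendecomposition of the
# pi-symmetrised generator (the GY chain is time-reversible)
gy_transition_matrix <- function(Q, pi, t) {
  sq <- sqrt(pi)
  S <- (sq * Q) %*% diag(1 / sq)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  P <- (eig$vectors * rep(exp(eig$values * t), each = nrow(Q))) %*% t(eig$vectors)
  P <- (1 / sq) * P %*% diag(sq)
  P[P < 0] <- 0
  P
}

# 61 x 61 table of aligned codon-pair counts
pair_count_matrix <- function(pair) {
  cc <- codon_columns(pair)
  cu <- codon_universe()
  N <- matrix(0, cu$n, cu$n)
  if (cc$n_used > 0L) {
    tab <- table(factor(cc$c1, levels = cu$codons),
                 factor(cc$c2, levels = cu$codons))
    N <- unclass(tab)
  }
  list(N = N, n_used = cc$n_used)
}

gy_loglik <- function(N, pi, kappa, omega, t) {
  gen <- gy_generator(kappa, omega, pi)
  P <- gy_transition_matrix(gen$Q, pi, t)
  M <- pi * P  # joint probability of an aligned codon pair
  nz <- N > 0
  if (any(M[nz] <= 0)) return(-Inf)
  sum(N[nz] * log(M[nz]))
}

#' ML Ks estimation under the GY model with F3x4 frequencies
#'
#' Fits `(t, kappa, omega)` to one aligned codon pair by bounded
#' multi-start maximum likelihood (starts drawn log-uniform within the
#' bounds, best of `n_restarts` kept), then converts the expected number
#' of substitutions per codon `t` into `dS` and `dN` through the fitted
#' generator's synonymous flux and site fractions.
#'
#' @param pair Character vector of two aligned in-frame sequences.
#' @param n_restarts Optimiser starts (default 5).
#' @param seed Integer seed for the start draws.
#' @param min_codons Minimum comparable codon columns (default 30).
#' @param bounds List of `t`, `kappa`, `omega` lower/upper bounds.
#' @return A `ks_estimate` list: `t`, `kappa`, `omega`, `dS`, `dN`,
#'   `lnL`, `method`, `n_codons`, `saturated`.
#' @export
gy94_fit <- function(pair, n_restarts = 5, seed = 1, min_codons = 30,
                     bounds = list(t = c(1e-4, 30), kappa = c(0.1, 20),
                                   omega = c(1e-3, 5))) {
  pc <- pair_count_matrix(pair)
  if (pc$n_used < min_codons) {
    stop(sprintf("only %d comparable codon columns (< %d)", pc$n_used, min_codons))
  }
  pi <- f3x4_freqs(pair)
  n_diff <- sum(pc$N[row(pc$N) != col(pc$N)])
  if (n_diff == 0) {
    return(ks_estimate(t = 0, kappa = NA_real_, omega = NA_real_,
                       dS = 0, dN = 0, lnL = gy_loglik(pc$N, pi, 2, 0.5, 1e-9),
                       method = "GY-F3x4", n_codons = pc$n_used,
                       saturated = FALSE))
  }
  lb <- log(c(bounds$t[1L], bounds$kappa[1L], bounds$omega[1L]))
  ub <- log(c(bounds$t[2L], bounds$kappa[2L], bounds$omega[2L]))
  negll <- function(theta) {
    if (any(theta < lb - 1e-12) || any(theta > ub + 1e-12)) return(1e10)
    v <- -gy_loglik(pc$N, pi, exp(theta[2L]), exp(theta[3L]), exp(theta[1L]))
    if (!is.finite(v)) 1e10 else v
  }
  set.seed(seed)
  starts <- t(replicate(n_restarts, stats::runif(3, lb, ub)))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    opt <- tryCatch(stats::optim(starts[r, ], negll, method = "Nelder-Mead",
                                 control = list(maxit = 800L, reltol = 1e-10)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all GY optimiser restarts failed")
  t_hat <- exp(best$par[1L]); kappa <- exp(best$par[2L]); omega <- exp(best$par[3L])
  dec <- ds_decomposition(kappa, omega, pi)
  saturated <- t_hat > 0.99 * bounds$t[2L]
  ks_estimate(t = t_hat, kappa = kappa, omega = omega,
              dS = t_hat * dec$rho_S / (3 * dec$f_S),
              dN = t_hat * (1 - dec$rho_S) / (3 * (1 - dec$f_S)),
              lnL = -best$value, method = "GY-F3x4", n_codons = pc$n_used,
              saturated = saturated)
}

ks_estimate <- function(t, kappa, omega, dS, dN, lnL, method, n_codons,
                        saturated) {
  structure(list(t = t, kappa = kappa, omega = omega, dS = dS, dN = dN,
                 lnL = lnL, method = method, n_codons = n_codons,
                 saturated = saturated), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("%s Ks estimate over %d codons: dS = %.4f, dN = %.4f%s\n",
              x$method, x$n_codons,
              ifelse(is.na(x$dS), NA, x$dS), ifelse(is.na(x$dN), NA, x$dN),
              if (isTRUE(x$saturated)) " [saturated]" else ""))
  invisible(x)
}

## ---- NG86 ---------------------------------------------------------------

# synonymous site count of one sense codon (stop mutations excluded from
# the per-position change set)
ng86_codon_sites <- function(codon, cu = codon_universe()) {
  ci <- strsplit(codon, "")[[1L]]
  aa <- cu$aa[cu$idx[codon]]
  s <- 0
  for (p in 1:3) {
    syn <- 0L; valid <- 0L
    for (b in setdiff(cu$nt, ci[p])) {
      cj <- ci; cj[p] <- b
      j <- cu$idx[paste(cj, collapse = "")]
      if (is.na(j)) next
      valid <- valid + 1L
      if (cu$aa[j] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  s
}

# average synonymous/nonsynonymous differences between two sense codons,
# pathway-averaged; pathways through stop codons are excluded (all-stop
# fallback: average over every pathway, stop steps counted nonsynonymous)
ng86_codon_diffs <- function(c1, c2, cu = codon_universe()) {
  d <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(d) == 0L) return(c(sd = 0, nd = 0))
  aa_of <- function(codon) {
    j <- cu$idx[codon]
    if (is.na(j)) "*" else cu$aa[j]
  }
  perms <- all_permutations(d)
  path_counts <- function(order) {
    cur <- strsplit(c1, "")[[1L]]
    tgt <- strsplit(c2, "")[[1L]]
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (p in order) {
      from <- paste(cur, collapse = "")
      cur[p] <- tgt[p]
      to <- paste(cur, collapse = "")
      a1 <- aa_of(from); a2 <- aa_of(to)
      if (a2 == "*" || a1 == "*") through_stop <- TRUE
      if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
    }
    c(sd, nd, through_stop)
  }
  res <- t(vapply(perms, path_counts, numeric(3)))
  ok <- res[, 3L] == 0
  if (any(ok)) res <- res[ok, , drop = FALSE]
  c(sd = mean(res[, 1L]), nd = mean(res[, 2L]))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' NG86 counting estimate of dS and dN
#'
#' Nei-Gojobori (1986): per-codon synonymous/nonsynonymous site counting
#' with stop mutations excluded, pathway-averaged difference counting,
#' and Jukes-Cantor correction. `dS` is flagged undefined (NA) when the
#' proportion of synonymous differences reaches the JC domain edge 3/4.
#'
#' @inheritParams gy94_fit
#' @return A `ks_estimate` (`kappa` is NA; `omega` = dN/dS when defined).
#' @export
ng86_ks <- function(pair, min_codons = 30) {
  cc <- codon_columns(pair)
  if (cc$n_used < min_codons) {
    stop(sprintf("only %d comparable codon columns (< %d)", cc$n_used, min_codons))
  }
  cu <- codon_universe()
  if (is.null(.pb_env$ng86_sites)) {
    .pb_env$ng86_sites <- vapply(cu$codons, ng86_codon_sites, numeric(1), cu = cu)
  }
  st <- .pb_env$ng86_sites
  S <- (sum(st[cc$c1]) + sum(st[cc$c2])) / 2
  N <- 3 * cc$n_used - S
  key <- paste(cc$c1, cc$c2)
  uniq <- !duplicated(key)
  dtab <- mapply(function(a, b) ng86_codon_diffs(a, b, cu = cu),
                 cc$c1[uniq], cc$c2[uniq])
  colnames(dtab) <- key[uniq]
  Sd <- sum(dtab["sd", key]); Nd <- sum(dtab["nd", key])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  ks_estimate(t = NA_real_, kappa = NA_real_,
              omega = if (!is.na(dS) && !is.na(dN) && dS > 0) dN / dS else NA_real_,
              dS = dS, dN = dN, lnL = NA_real_, method = "NG86",
              n_codons = cc$n_used, saturated = is.na(dS))
}
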