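## Redundancy correction of within-family Ks estimates: recursive clade
## splitting at saturated Ks, then per-duplication-node weighting so each
## duplication event contributes total weight one to the age distribution.

# children of every node, and the leaf set under every node
tree_structure <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[k, 2L])
  }
  leaves <- vector("list", n_node)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (tip in seq_len(n_tip)) leaves[[tip]] <- tree$tip.label[tip]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; c2 <- tr$edge[k, 2L]
    leaves[[p]] <- c(leaves[[p]], leaves[[c2]])
  }
  list(kids = kids, leaves = leaves, n_tip = n_tip, root = n_tip + 1L)
}

# all pairwise ks within `labs` at most `threshold` and none missing
clade_within_threshold <- function(labs, ks, threshold) {
  if (length(labs) < 2L) return(TRUE)
  sub <- ks[labs, labs]
  vals <- sub[upper.tri(sub)]
  !anyNA(vals) && all(vals <= threshold)
}

#' Split a gene tree recursively at saturated Ks
#'
#' Starting at the root, a clade whose internal pairwise Ks estimates all
#' stay at or below `threshold` is kept whole; otherwise it is replaced
#' by its child clades and the test recurses. A missing (e.g. saturated
#' NG86) Ks inside a clade counts as above threshold, which is the
#' conservative choice. Singleton leaves are returned as singleton
#' clades.
#'
#' @param tree Rooted `phylo` gene tree (polytomies are resolved
#'   deterministically first).
#' @param ks Symmetric matrix of pairwise Ks with leaf labels as
#'   dimnames; `NA` for missing/saturated estimates.
#' @param threshold Splitting threshold (default 5).
#' @return List of character vectors: the leaf sets of the resulting
#'   subclades (in root-to-leaf discovery order).
#' @export
split_by_ks <- function(tree, ks, threshold = 5) {
  tree <- resolve_polytomies(tree)
  if (!all(tree$tip.label %in% rownames(ks))) {
    stop("ks matrix is missing rows for some leaves")
  }
  ts <- tree_structure(tree)
  out <- list()
  recurse <- function(node) {
    labs <- ts$leaves[[node]]
    if (clade_within_threshold(labs, ks, threshold)) {
      out[[length(out) + 1L]] <<- labs
    } else {
      for (ch in ts$kids[[node]]) recurse(ch)
    }
  }
  recurse(ts$root)
  out
}

# subtree of `tree` spanning `labs`, preserving internal structure
clade_subtree <- function(tree, labs) {
  if (length(labs) < 2L) return(NULL)
  ape::keep.tip(tree, labs)
}

#' Node-weighted Ks samples for one subclade
#'
#' Every internal node of the (binary) subclade is treated as one
#' duplication event. A node whose child clades hold `a` and `b` leaves
#' spans `m = a*b` cross pairs; each cross-pair Ks enters the
#' distribution with weight `1/m`, so the weights for one duplication
#' event sum to one. Cross pairs with missing Ks are skipped and the
#' weights renormalised over the remaining pairs of that node; a node
#' with no usable pair contributes nothing.
#'
#' @param subtree Rooted binary `phylo` over the subclade's leaves.
#' @param ks Pairwise Ks matrix (dimnames = leaf labels).
#' @param node_prefix Prefix for duplication-node ids in the output.
#' @return data.frame with columns `ks`, `weight`, `node`.
#' @export
node_weighted_ks <- function(subtree, ks, node_prefix = "n") {
  ts <- tree_structure(subtree)
  rows <- list()
  for (node in (ts$n_tip + 1L):(ts$n_tip + subtree$Nnode)) {
    ch <- ts$kids[[node]]
    if (length(ch) != 2L) stop("subclade tree must be binary")
    a <- ts$leaves[[ch[1L]]]; b <- ts$leaves[[ch[2L]]]
    pairs <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    vals <- ks[cbind(pairs$a, pairs$b)]
    ok <- !is.na(vals)
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      ks = vals[ok], weight = 1 / sum(ok),
      node = paste0(node_prefix, node), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(ks = numeric(), weight = numeric(), node = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Build the node-weighted Ks distribution over a set of gene families
#'
#' For each family: midpoint-root the gene tree if unrooted, resolve
#' polytomies, split recursively at `threshold`, and collect
#' per-duplication-node weighted Ks samples from every multi-leaf
#' subclade. Families with fewer than two leaves are skipped (recorded
#' in the `skipped` attribute).
#'
#' @param families List of `list(tree = phylo, ks = matrix,
#'   family_id = chr)`.
#' @param threshold Clade-splitting Ks threshold (default 5).
#' @return data.frame with columns `family`, `node`, `ks`, `weight`.
#' @export
build_weighted_distribution <- function(families, threshold = 5) {
  out <- list(); skipped <- character()
  for (fam in families) {
    id <- fam$family_id
    tree <- fam$tree
    if (is.null(tree) || length(tree$tip.label) < 2L) {
      skipped <- c(skipped, id)
      next
    }
    if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
    tree <- resolve_polytomies(tree)
    clades <- split_by_ks(tree, fam$ks, threshold)
    for (ci in seq_along(clades)) {
      labs <- clades[[ci]]
      if (length(labs) < 2L) next
      sub <- clade_subtree(tree, labs)
      w <- node_weighted_ks(sub, fam$ks, node_prefix = paste0(id, ".c", ci, ".n"))
      if (nrow(w) > 0L) {
        w$family <- id
        out[[length(out) + 1L]] <- w
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(ks = numeric(), weight = numeric(), node = character(),
               family = character(), stringsAsFactors = FALSE)
  res <- res[, c("family", "node", "ks", "weight")]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}
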