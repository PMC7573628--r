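#' Parse a newick tree string or file
#'
#' Thin wrapper around [ape::read.tree()] with the validation this package
#' needs: duplicate leaf labels are an error, and a syntactically broken
#' string raises a parse error rather than returning `NULL`.
#'
#' @param text A newick string (terminated by `;`). Exactly one of `text`
#'   and `file` must be given.
#' @param file Path to a newick file.
#' @return An object of class `phylo`. Polytomies are allowed on read.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("give exactly one of `text` or `file`")
  }
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop(sprintf("newick parse error: %d '(' vs %d ')'", n_open, n_close))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ", conditionMessage(e)),
                 warning = function(w) stop("newick parse error: ", conditionMessage(w)))
  if (is.null(tr)) stop("newick parse error: unparseable string")
  if (anyDuplicated(tr$tip.label)) {
    dup <- tr$tip.label[duplicated(tr$tip.label)][1L]
    stop("duplicate leaf name in newick: ", dup)
  }
  tr
}

#' Write a tree to newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' The 11-taxon angiosperm time tree used throughout the examples
#'
#' Ultrametric tree (branch lengths in Myr) over Moringa (`Mob`) and ten
#' other flowering plants, reconstructed from the published topology with
#' TimeTree-style median divergence ages: Amborella (`Atr`) sister to all
#' other angiosperms, the magnoliid avocado (`Pah`) sister to the
#' monocot + eudicot clade.
#'
#' @return A `phylo` object with 11 tips.
#' @export
species_tree_11 <- function() {
  parse_newick(file = system.file("extdata", "species_tree_11taxa.nwk",
                                  package = "plastburst", mustWork = TRUE))
}

#' Check that a rooted tree is ultrametric
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param rel_tol Relative tolerance on root-to-leaf depths.
#' @return `TRUE`/`FALSE`.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  diff(range(d)) <= rel_tol * max(max(d), .Machine$double.eps)
}

# root-to-node path lengths for every node of a rooted phylo
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  # edges in preorder: parents appear before children when reordered
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2L]] <- depth[tr$edge[k, 1L]] + tr$edge.length[k]
  }
  depth
}

#' Midpoint-root a gene tree
#'
#' Places the root halfway along the longest leaf-to-leaf path. Path
#' lengths between leaves are preserved.
#'
#' @param tree A `phylo` with branch lengths (rooted or unrooted).
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("midpoint rooting needs branch lengths on every edge")
  }
  if (length(tree$tip.label) < 2L) stop("need at least 2 leaves")
  phangorn::midpoint(tree)
}

#' Resolve polytomies deterministically
#'
#' Multifurcations are resolved left-to-right into binary nodes joined by
#' zero-length branches, so downstream duplication-node weighting sees a
#' binary tree. Deterministic: no randomness.
#'
#' @param tree A `phylo`.
#' @return A binary `phylo`.
#' @export
resolve_polytomies <- function(tree) {
  ape::multi2di(tree, random = FALSE)
}

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Twelve tab-separated columns: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore. Minus-strand hits
#' (sstart > send) are normalised so the stored subject interval always has
#' `sstart <= send`, with `strand = "-"`.
#'
#' @param path Path to the tabular file.
#' @return A data.frame with one row per hit and an extra `strand` column.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_hits())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1L]
    stop(sprintf("line %d: expected 12 tab-separated columns, found %d",
                 bad, ncols[bad]))
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric %s field", which(is.na(v))[1L], what))
    }
    v
  }
  hits <- data.frame(
    query_id     = m[, 1L],
    subject_id   = m[, 2L],
    pct_identity = num(3L, "identity"),
    aln_length   = as.integer(num(4L, "length")),
    mismatches   = as.integer(num(5L, "mismatch")),
    gap_opens    = as.integer(num(6L, "gapopen")),
    qstart       = as.integer(num(7L, "qstart")),
    qend         = as.integer(num(8L, "qend")),
    sstart       = as.integer(num(9L, "sstart")),
    send         = as.integer(num(10L, "send")),
    evalue       = num(11L, "evalue"),
    bitscore     = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(hits$qstart > hits$qend) || any(hits$qstart < 1L)) {
    stop("invalid query coordinates: need 1 <= qstart <= qend")
  }
  if (any(hits$pct_identity < 0 | hits$pct_identity > 100)) {
    stop("percent identity outside [0, 100]")
  }
  if (any(hits$aln_length < 1L)) stop("alignment length < 1")
  minus <- hits$sstart > hits$send
  tmp <- hits$sstart[minus]
  hits$sstart[minus] <- hits$send[minus]
  hits$send[minus] <- tmp
  hits$strand <- ifelse(minus, "-", "+")
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Read a gene-family count table
#'
#' TSV with a header row of species names; first column = family id;
#' remaining columns non-negative integer gene counts.
#'
#' @param path TSV path.
#' @return An integer matrix, families x species, with dimnames.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a family-id column plus >= 1 species")
  fam <- as.character(df[[1L]])
  if (anyDuplicated(fam)) stop("duplicate family ids in count table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("non-numeric count in table")
  if (any(m < 0)) stop("negative count in table")
  if (any(m != round(m))) stop("non-integer count in table")
  storage.mode(m) <- "integer"
  rownames(m) <- fam
  m
}

#' Write a gene-family count table
#' @param counts Integer matrix families x species.
#' @param path Output TSV path.
#' @export
write_counts_table <- function(counts, path) {
  df <- data.frame(family_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-GO annotation table
#'
#' Two tab-separated columns, `gene_id` and `term_id`; one term per line,
#' no header required (a `gene_id` header line is tolerated).
#'
#' @param path TSV path.
#' @return A named list mapping gene id to a character vector of term ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "term_id"))
  if (nrow(df) > 0L && df$gene_id[1L] %in% c("gene_id", "gene")) {
    df <- df[-1L, , drop = FALSE]
  }
  if (any(!nzchar(df$term_id))) stop("empty GO term id in annotation table")
  lapply(split(df$term_id, df$gene_id), unique)
}

#' Read an in-frame codon FASTA alignment
#'
#' All sequences must have equal length divisible by 3.
#'
#' @param path FASTA path.
#' @return A named character vector of aligned sequences (upper case).
#' @export
read_codon_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("ragged alignment: sequence lengths %s",
                 paste(unique(lens), collapse = ", ")))
  }
  if (lens[1L] %% 3L != 0L) {
    stop(sprintf("alignment length %d is not a multiple of 3", lens[1L]))
  }
  seqs
}

#' Read a two-column syntenic gene-pair list
#' @param path TSV path (columns: gene1, gene2; optional header).
#' @return data.frame with columns `gene1`, `gene2`.
#' @export
read_syntenic_pairs <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene1", "gene2"))
  if (nrow(df) > 0L && df$gene1[1L] %in% c("gene1", "gene_1")) {
    df <- df[-1L, , drop = FALSE]
  }
  df
}
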