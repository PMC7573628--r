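## GO-term over/under-representation in a gene subset versus the genome:
## two-sided Fisher's exact tests with Bonferroni family-wise correction.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of every
#' table with the same margins whose probability does not exceed that of
#' the observed table (with the customary small relative slack for
#' floating-point ties). An all-zero table has p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cell counts; rows are
#'   subset/rest, columns are with-term/without-term.
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) return(1)
  stats::fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
}

#' GO-term enrichment by Fisher's exact test with Bonferroni correction
#'
#' Tests every term annotating at least one universe gene for a
#' differential distribution between the subset and the rest of the
#' universe. The universe defaults to all annotated genes. Direction is
#' read off the sample odds ratio (with a Haldane 0.5 correction on zero
#' cells, for reporting only); significance is Bonferroni-corrected p
#' below `alpha`.
#'
#' @param subset Character vector of gene ids (must lie in the universe).
#' @param annotations Named list, gene id -> character vector of term
#'   ids (as from [read_annotations()]).
#' @param universe Character vector of gene ids; default
#'   `names(annotations)`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return data.frame, one row per tested term: `term`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p`, `p_bonferroni`, `direction`, `significant`;
#'   sorted by p.
#' @export
enrich_terms <- function(subset, annotations, universe = NULL, alpha = 0.05) {
  if (is.null(universe)) universe <- names(annotations)
  universe <- unique(universe)
  subset <- unique(subset)
  missing <- setdiff(subset, universe)
  if (length(missing)) {
    stop("subset genes absent from universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  ann <- annotations[intersect(names(annotations), universe)]
  gene2term <- rep(names(ann), lengths(ann))
  term_of <- unlist(ann, use.names = FALSE)
  in_subset <- gene2term %in% subset
  n_sub <- length(subset)
  n_uni <- length(universe)
  terms <- sort(unique(term_of))
  a <- vapply(split(in_subset, term_of)[terms], sum, numeric(1))
  term_total <- vapply(split(in_subset, term_of)[terms], length, numeric(1))
  b <- n_sub - a
  c_ <- term_total - a
  d <- (n_uni - n_sub) - c_
  m <- length(terms)
  p <- vapply(seq_len(m),
              function(i) fisher_exact_2x2(a[i], b[i], c_[i], d[i]),
              numeric(1))
  p_bonf <- stats::p.adjust(p, method = "bonferroni")
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  res <- data.frame(term = terms, a = as.integer(a), b = as.integer(b),
                    c = as.integer(c_), d = as.integer(d),
                    odds_ratio = or, p = p, p_bonferroni = p_bonf,
                    direction = ifelse(or >= 1, "over", "under"),
                    significant = p_bonf < alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term), ]
  rownames(res) <- NULL
  res
}
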