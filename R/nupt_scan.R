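## Quantification of plastid-DNA insertions (NUPTs) in a nuclear assembly
## from local-alignment hit tables: genome fraction, size-distribution
## statistics, scaffold selection for circular plots, and identity-ratio
## colour bins for Circos link files.

# union length of a set of 1-based inclusive intervals
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0L; cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Summarise plastid-DNA insertions in a nuclear genome
#'
#' With `merge = FALSE` (the default) every local-alignment hit counts
#' as one insertion and the total aligned region is the plain sum of hit
#' alignment lengths, so `mean = total / n_hits` holds by construction.
#' With `merge = TRUE` subject intervals are unioned per scaffold before
#' totalling, which cannot exceed the genome size.
#'
#' @param hits data.frame of hits as from [read_blast_tab()].
#' @param genome_bp Total assembled nuclear genome size in bp.
#' @param merge Union-merge overlapping subject intervals per scaffold?
#' @param scaffold_lengths Optional named vector; if supplied, a hit on
#'   an unknown scaffold is an error.
#' @param over_bp Threshold for the "scaffolds with more than this many
#'   aligned bp" count (default 2000).
#' @return A `nupt_summary` list: `n_hits`, `n_scaffolds_hit`,
#'   `total_aligned_bp`, `genome_bp`, `fraction`, `min_len`, `max_len`,
#'   `mean_len`, `median_len`, `per_scaffold` (named totals),
#'   `n_scaffolds_over`.
#' @export
summarize_nupt <- function(hits, genome_bp, merge = FALSE,
                           scaffold_lengths = NULL, over_bp = 2000) {
  if (genome_bp <= 0) stop("genome_bp must be positive")
  if (!is.null(scaffold_lengths)) {
    unknown <- setdiff(unique(hits$subject_id), names(scaffold_lengths))
    if (length(unknown)) stop("hits on unknown scaffolds: ",
                              paste(unknown, collapse = ", "))
  }
  if (nrow(hits) == 0L) {
    return(structure(list(n_hits = 0L, n_scaffolds_hit = 0L,
                          total_aligned_bp = 0, genome_bp = genome_bp,
                          fraction = 0, min_len = NA, max_len = NA,
                          mean_len = NA, median_len = NA,
                          per_scaffold = numeric(0), n_scaffolds_over = 0L,
                          merge = merge), class = "nupt_summary"))
  }
  per_scaffold <- if (merge) {
    vapply(split(hits, hits$subject_id),
           function(h) as.numeric(interval_union_length(h$sstart, h$send)),
           numeric(1))
  } else {
    vapply(split(hits$aln_length, hits$subject_id), sum, numeric(1))
  }
  total <- sum(per_scaffold)
  structure(list(
    n_hits = nrow(hits),
    n_scaffolds_hit = length(per_scaffold),
    total_aligned_bp = total,
    genome_bp = genome_bp,
    fraction = total / genome_bp,
    min_len = min(hits$aln_length),
    max_len = max(hits$aln_length),
    mean_len = mean(hits$aln_length),
    median_len = stats::median(hits$aln_length),
    per_scaffold = per_scaffold,
    n_scaffolds_over = sum(per_scaffold > over_bp),
    merge = merge
  ), class = "nupt_summary")
}

#' @export
print.nupt_summary <- function(x, ...) {
  cat(sprintf("%d hits on %d scaffolds; %s bp aligned (%.2f%% of %s bp)%s\n",
              x$n_hits, x$n_scaffolds_hit,
              format(x$total_aligned_bp, big.mark = ","),
              100 * x$fraction, format(x$genome_bp, big.mark = ","),
              if (x$merge) " [interval-merged]" else ""))
  if (x$n_hits > 0L) {
    cat(sprintf("hit lengths %d-%d bp, mean %.0f, median %.0f; %d scaffolds > %s aligned bp\n",
                x$min_len, x$max_len, x$mean_len, x$median_len,
                x$n_scaffolds_over, "2000"))
  }
  invisible(x)
}

#' Select scaffolds for the circular insertion plot
#'
#' Keeps scaffolds at least as long as the plastid genome that carry at
#' least one hit with identity `>= min_identity` percent over
#' `>= min_span` bp, ordered by total aligned bp (descending), i.e. the
#' clockwise plotting order.
#'
#' @param hits Hit data.frame.
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param plastid_bp Plastid genome length (bp).
#' @param min_identity Minimum percent identity of the qualifying hit.
#' @param min_span Minimum alignment length of the qualifying hit (bp).
#' @return Character vector of scaffold ids, ordered.
#' @export
select_plot_scaffolds <- function(hits, scaffold_lengths, plastid_bp,
                                  min_identity = 90, min_span = 2000) {
  unknown <- setdiff(unique(hits$subject_id), names(scaffold_lengths))
  if (length(unknown)) stop("no length for scaffolds: ",
                            paste(unknown, collapse = ", "))
  qual <- hits$pct_identity >= min_identity & hits$aln_length >= min_span
  cand <- unique(hits$subject_id[qual])
  cand <- cand[scaffold_lengths[cand] >= plastid_bp]
  if (length(cand) == 0L) return(character(0))
  totals <- vapply(split(hits$aln_length[hits$subject_id %in% cand],
                         hits$subject_id[hits$subject_id %in% cand]),
                   sum, numeric(1))
  names(sort(totals, decreasing = TRUE))
}

#' Colour-bin alignment links by relative identity
#'
#' Circoletto-style colouring: with percent identity as the score, each
#' hit gets `ratio = (score - min) / (max - min)` over the hit set and a
#' colour bin: blue for ratio <= 0.25, green <= 0.50, orange <= 0.75,
#' red > 0.75. When all identities are equal the ratio is defined as 1,
#' so a uniform set is drawn red.
#'
#' @param hits Hit data.frame (>= 1 row).
#' @return data.frame: query/subject intervals, `pct_identity`, `ratio`,
#'   `color`.
#' @export
color_links <- function(hits) {
  if (nrow(hits) < 1L) stop("need at least one hit")
  score <- hits$pct_identity
  rng <- range(score)
  ratio <- if (rng[1L] == rng[2L]) rep(1, length(score)) else
    (score - rng[1L]) / (rng[2L] - rng[1L])
  color <- cut(ratio, breaks = c(-Inf, 0.25, 0.50, 0.75, Inf),
               labels = c("blue", "green", "orange", "red"))
  data.frame(query_id = hits$query_id, qstart = hits$qstart, qend = hits$qend,
             subject_id = hits$subject_id, sstart = hits$sstart,
             send = hits$send, pct_identity = score, ratio = ratio,
             color = as.character(color), stringsAsFactors = FALSE)
}

#' Write a Circos link table
#'
#' Tab-separated `chr start end chr start end color=<bin>` rows, one per
#' link, ready for the Circos `links` block.
#'
#' @param links data.frame from [color_links()].
#' @param path Output path.
#' @export
write_circos_links <- function(links, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\tcolor=%s",
                   links$query_id, links$qstart, links$qend,
                   links$subject_id, links$sstart, links$send, links$color)
  writeLines(lines, path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Toy ungapped seed-and-extend local aligner
#'
#' Exact word seeding on both strands with two-sided x-drop extension
#' and per-diagonal merging of overlapping hits. Built for self-contained
#' fixtures and synthetic-genome recovery checks; it is not a
#' replacement for a gapped local aligner (no gaps, no e-value theory —
#' the reported e-value is the crude `m * n * 2^-score`).
#'
#' @param query,subject Sequences over ACGT (character scalars).
#' @param word Seed word size (default 9).
#' @param match,mismatch Match/mismatch scores (defaults +1 / -2).
#' @param xdrop Extension drop-off (default 20).
#' @param min_score Minimum reported score (default 25).
#' @param query_id,subject_id Ids used in the output table.
#' @return A hit data.frame in the layout of [read_blast_tab()]; minus
#'   strand hits carry subject coordinates on the forward strand with
#'   `strand == "-"`.
#' @export
toy_local_align <- function(query, subject, word = 9, match = 1,
                            mismatch = -2, xdrop = 20, min_score = 25,
                            query_id = "query", subject_id = "subject") {
  stopifnot(nchar(query) >= word, nchar(subject) >= word)
  slen <- nchar(subject)
  as_hits <- function(raw, strand) {
    n <- length(raw$qstart)
    if (n == 0L) return(empty_hits())
    sstart <- raw$sstart; send <- raw$send
    if (strand == "-") {
      tmp <- slen - raw$send + 1L
      send <- slen - raw$sstart + 1L
      sstart <- tmp
    }
    matches <- raw$length - raw$mismatch
    data.frame(query_id = query_id, subject_id = subject_id,
               pct_identity = 100 * matches / raw$length,
               aln_length = as.integer(raw$length),
               mismatches = as.integer(raw$mismatch),
               gap_opens = 0L,
               qstart = as.integer(raw$qstart), qend = as.integer(raw$qend),
               sstart = as.integer(sstart), send = as.integer(send),
               evalue = nchar(query) * as.numeric(slen) * 2^(-raw$score),
               bitscore = raw$score,
               strand = strand, stringsAsFactors = FALSE)
  }
  plus <- as_hits(cpp_seed_extend(query, subject, word, match, mismatch,
                                  xdrop, min_score), "+")
  minus <- as_hits(cpp_seed_extend(query, revcomp(subject), word, match,
                                   mismatch, xdrop, min_score), "-")
  rbind(plus, minus)
}
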