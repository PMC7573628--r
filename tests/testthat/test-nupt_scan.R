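fake_hits <- function(lens, scaf = "s1", sstart = NULL, ident = 95) {
  n <- length(lens)
  if (is.null(sstart)) sstart <- cumsum(c(1, head(lens, -1) + 100))
  data.frame(query_id = "cp", subject_id = rep_len(scaf, n),
             pct_identity = rep_len(ident, n), aln_length = as.integer(lens),
             mismatches = 0L, gap_opens = 0L,
             qstart = 1L, qend = as.integer(lens),
             sstart = as.integer(sstart),
             send = as.integer(sstart + lens - 1),
             evalue = 0, bitscore = lens, strand = "+",
             stringsAsFactors = FALSE)
}

test_that("insertion summaries reproduce the sum-of-hits arithmetic", {
  s <- summarize_nupt(fake_hits(c(100, 200, 300)), genome_bp = 10000)
  expect_equal(s$total_aligned_bp, 600)
  expect_equal(s$fraction, 0.06)
  expect_equal(s$mean_len, 200)
  expect_equal(s$median_len, 200)
  expect_equal(s$min_len, 100)
  expect_equal(s$max_len, 300)
  expect_equal(s$mean_len, s$total_aligned_bp / s$n_hits)  # paper arithmetic
  s2 <- summarize_nupt(fake_hits(c(100, 200, 300, 400)), genome_bp = 10000)
  expect_equal(s2$median_len, 250)  # midpoint convention for even n
})

test_that("interval merging unions overlaps and bounds the fraction", {
  two <- fake_hits(c(100, 100), sstart = c(1, 1))  # fully overlapping
  expect_equal(summarize_nupt(two, 1000, merge = FALSE)$total_aligned_bp, 200)
  expect_equal(summarize_nupt(two, 1000, merge = TRUE)$total_aligned_bp, 100)
  set.seed(3)
  rnd <- fake_hits(sample(50:500, 30, TRUE),
                   scaf = sample(c("a", "b"), 30, TRUE),
                   sstart = sample(1:5000, 30))
  m_on <- summarize_nupt(rnd, 6000, merge = TRUE)
  m_off <- summarize_nupt(rnd, 6000, merge = FALSE)
  expect_lte(m_on$total_aligned_bp, m_off$total_aligned_bp)
  expect_lte(m_on$fraction, 1)
  expect_equal(m_on$total_aligned_bp, sum(m_on$per_scaffold))
})

test_that("hits on unknown scaffolds are rejected when lengths are supplied", {
  h <- fake_hits(100, scaf = "mystery")
  expect_error(summarize_nupt(h, 1000, scaffold_lengths = c(s1 = 500)),
               "unknown scaffold")
})

test_that("plot-scaffold selection applies length, identity and span rules", {
  lens <- c(big = 200000, small = 100000, big2 = 250000)
  h <- rbind(fake_hits(2500, scaf = "big", ident = 95),
             fake_hits(2500, scaf = "small", ident = 95),
             fake_hits(1900, scaf = "big2", ident = 99))
  sel <- select_plot_scaffolds(h, lens, plastid_bp = 160600)
  expect_equal(sel, "big")       # small fails length, big2 fails span
  h2 <- rbind(h, fake_hits(c(3000, 4000), scaf = "big2", ident = 92))
  sel2 <- select_plot_scaffolds(h2, lens, plastid_bp = 160600)
  expect_equal(sel2, c("big2", "big"))  # ordered by total aligned bp
})

test_that("identity colour bins follow the min-max ratio rule", {
  h <- fake_hits(rep(1000, 4), ident = 1)
  h$pct_identity <- c(80, 90, 95, 100)
  links <- color_links(h)
  expect_equal(links$color, c("blue", "green", "orange", "red"))
  expect_equal(links$ratio[2], 0.5)
  expect_equal(links$color[links$pct_identity == 80], "blue")  # ratio 0
  same <- fake_hits(rep(500, 3), ident = 97)
  expect_equal(unique(color_links(same)$color), "red")  # degenerate: all red
  f <- tempfile()
  write_circos_links(links, f)
  lines <- readLines(f)
  expect_length(lines, 4)
  expect_match(lines[1], "^cp\t1\t1000\ts1\t\\d+\t\\d+\tcolor=blue$")
})

test_that("the toy aligner recovers exact, mutated and reverse copies", {
  set.seed(11)
  q <- plastburst:::random_dna(3000)
  bg <- plastburst:::random_dna(20000)
  insert <- substr(q, 1001, 1500)
  subject <- paste0(substr(bg, 1, 5000), insert, substr(bg, 5501, 20000))
  hits <- toy_local_align(q, subject)
  exact <- hits[hits$aln_length >= 450, ]
  expect_equal(nrow(exact), 1)
  expect_equal(exact$pct_identity, 100)
  expect_gte(exact$aln_length, 500)
  expect_equal(exact$strand, "+")

  mut <- plastburst:::mutate_dna(insert, 0.05)
  subject2 <- paste0(substr(bg, 1, 5000), mut, substr(bg, 5501, 20000))
  hits2 <- toy_local_align(q, subject2)
  big2 <- hits2[which.max(hits2$aln_length), ]
  expect_gte(big2$aln_length, 300)
  expect_true(big2$pct_identity >= 92 && big2$pct_identity <= 98)

  rc <- plastburst:::revcomp(insert)
  subject3 <- paste0(substr(bg, 1, 5000), rc, substr(bg, 5501, 20000))
  hits3 <- toy_local_align(q, subject3)
  best3 <- hits3[which.max(hits3$aln_length), ]
  expect_equal(best3$strand, "-")
  expect_gte(best3$aln_length, 450)
  # minus-strand subject interval is reported on the forward strand
  expect_true(best3$sstart >= 4900 && best3$send <= 5600)
})

test_that("an insertion-free genome yields no hits above chance", {
  sim <- sim_nupt_genome(100000, 5000, n_insertions = 0, seed = 19)
  hits <- toy_local_align(sim$plastid, sim$nuclear)
  expect_equal(nrow(hits), 0)
})
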