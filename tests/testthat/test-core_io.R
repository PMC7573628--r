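test_that("newick parse/write round trip preserves topology, labels and lengths", {
  set.seed(101)
  for (n in c(2, 5, 17)) {
    tr <- ape::rtree(n)
    back <- parse_newick(text = write_newick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr); d2 <- ape::cophenetic.phylo(back)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
  }
  two <- parse_newick(text = "(A:1,B:1):0;")
  expect_equal(sort(two$tip.label), c("A", "B"))
  expect_equal(unname(ape::node.depth.edgelength(two)[1:2]), c(1, 1))
})

test_that("malformed or duplicated newick input is rejected", {
  expect_error(parse_newick(text = "(A,(B,C);"), "parse error")
  expect_error(parse_newick(text = "(A:1,A:1);"), "duplicate")
  expect_error(parse_newick(text = "(A:1,B:1);", file = "x"), "exactly one")
})

test_that("the bundled 11-species time tree is ultrametric with 11 leaves", {
  tr <- species_tree_11()
  expect_length(tr$tip.label, 11)
  expect_true(all(c("Mob", "Ath", "Atr", "Vvi", "Zma") %in% tr$tip.label))
  expect_true(is_ultrametric(tr))
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting bisects the tree diameter and is idempotent", {
  cherry <- midpoint_root(parse_newick(text = "(A:1,B:1);"))
  dd <- ape::node.depth.edgelength(cherry)
  expect_equal(unname(dd[1:2]), c(1, 1))

  tr <- parse_newick(text = "((A:1,B:4):1,C:1);")
  rooted <- midpoint_root(ape::unroot(tr))
  pd <- ape::cophenetic.phylo(rooted)
  expect_equal(max(pd), 6)  # diameter preserved
  depths <- ape::node.depth.edgelength(rooted)[seq_along(rooted$tip.label)]
  expect_equal(max(depths), 3, tolerance = 1e-9)  # root bisects the 6.0 path

  # property over random trees: root equidistant (= diameter/2) from the
  # two farthest leaves; all leaf-leaf path lengths unchanged
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::unroot(ape::rtree(8))
    rooted <- midpoint_root(tr)
    d_in <- ape::cophenetic.phylo(tr)
    d_out <- ape::cophenetic.phylo(rooted)
    expect_equal(d_out[rownames(d_in), colnames(d_in)], d_in, tolerance = 1e-9)
    depths <- ape::node.depth.edgelength(rooted)[seq_along(rooted$tip.label)]
    expect_equal(max(depths), max(d_in) / 2, tolerance = 1e-9)
    again <- midpoint_root(rooted)
    expect_equal(suppressWarnings(ape::dist.topo(again, rooted)[1]), 0)
  }
})

test_that("midpoint rooting requires branch lengths", {
  tr <- parse_newick(text = "((A,B),C);")
  expect_error(midpoint_root(tr), "branch lengths")
})

make_blast_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("BLAST tabular reading parses and normalises strand", {
  f <- make_blast_file(c(
    "cp\tscaf1\t98.5\t2000\t30\t0\t1\t2000\t5001\t7000\t0.0\t3600",
    "cp\tscaf2\t91.0\t500\t45\t0\t10\t509\t7000\t6501\t1e-50\t800"))
  hits <- read_blast_tab(f)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$aln_length, c(2000L, 500L))
  expect_equal(hits$strand, c("+", "-"))
  expect_equal(hits$sstart[2], 6501L)  # minus strand stored start <= end
  expect_equal(hits$send[2], 7000L)
})

test_that("BLAST tabular errors carry the offending line number", {
  f <- make_blast_file(c(
    "cp\tscaf1\t98.5\t2000\t30\t0\t1\t2000\t5001\t7000\t0.0\t3600",
    "cp\tscaf1\t98.5\t2000\t30\t0\t1\t2000\t5001\t7000\t0.0"))
  expect_error(read_blast_tab(f), "line 2")
  f2 <- make_blast_file("cp\tscaf1\tNOTNUM\t2000\t30\t0\t1\t2000\t1\t2000\t0.0\t3600")
  expect_error(read_blast_tab(f2), "line 1.*identity")
})

test_that("parsed alignment lengths agree with a line-by-line oracle", {
  set.seed(5)
  lines <- vapply(1:40, function(i) {
    len <- sample(30:5000, 1)
    s <- sample(1:1e6, 1)
    paste(c("cp", paste0("s", sample(1:8, 1)), sprintf("%.1f", runif(1, 80, 100)),
            len, sample(0:50, 1), 0, 1, len, s, s + len - 1,
            "1e-10", len), collapse = "\t")
  }, character(1))
  f <- make_blast_file(lines)
  hits <- read_blast_tab(f)
  oracle_total <- sum(vapply(readLines(f), function(l)
    as.numeric(strsplit(l, "\t")[[1]][4]), numeric(1)))
  expect_identical(sum(hits$aln_length), as.integer(oracle_total))
})

test_that("count tables round-trip and invalid counts are rejected", {
  m <- matrix(c(0L, 3L, 1L, 2L, 5L, 0L), nrow = 2,
              dimnames = list(c("og1", "og2"), c("A", "B", "C")))
  f <- tempfile()
  write_counts_table(m, f)
  expect_identical(read_counts_table(f), m)

  fneg <- tempfile()
  writeLines(c("family_id\tA\tB", "og1\t-1\t2"), fneg)
  expect_error(read_counts_table(fneg), "negative")
})

test_that("annotation tables map genes to unique term sets", {
  f <- tempfile()
  writeLines(c("g1\tGO:1", "g1\tGO:2", "g1\tGO:1", "g2\tGO:3"), f)
  ann <- read_annotations(f)
  expect_equal(sort(ann$g1), c("GO:1", "GO:2"))
  expect_equal(ann$g2, "GO:3")
})

test_that("codon FASTA reading enforces equal in-frame lengths", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">a", strrep("ATG", 100), ">b", strrep("ATA", 100)), f)
  seqs <- read_codon_fasta(f)
  expect_equal(unname(nchar(seqs)), c(300L, 300L))

  f2 <- tempfile(fileext = ".fa")
  writeLines(c(">a", strrep("ATG", 100), ">b", substr(strrep("ATA", 100), 1, 299)), f2)
  expect_error(read_codon_fasta(f2), "ragged")

  f3 <- tempfile(fileext = ".fa")
  writeLines(c(">a", strrep("ATGA", 25), ">b", strrep("ATGA", 25)), f3)
  expect_error(read_codon_fasta(f3), "multiple of 3")
})
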