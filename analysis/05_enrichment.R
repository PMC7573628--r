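#!/usr/bin/env Rscript
# Stage 5: GO-term enrichment of a gene subset against the annotated
# genome by Fisher's exact test with Bonferroni correction. The subset
# here is a simulated "expanded families" gene set with one planted
# over-represented term and one planted under-represented term.

suppressPackageStartupMessages(library(plastburst))

master_seed <- 20260930
dir.create("results", showWarnings = FALSE)
set.seed(substream(master_seed, 50))

genes <- sprintf("g%05d", 1:5000)
subset <- genes[1:250]
ann <- lapply(stats::setNames(genes, genes), function(g) character(0))
# background terms, independent of the subset
for (k in 1:150) {
  members <- sample(genes, rpois(1, 60))
  for (g in members) ann[[g]] <- c(ann[[g]], sprintf("GO:%07d", k))
}
# planted signal: "plastid" term on 60% of the subset but 3% of the rest
for (g in c(sample(subset, 150), sample(setdiff(genes, subset), 140))) {
  ann[[g]] <- c(ann[[g]], "GO:0009536")  # plastid
}
# planted depletion: a term common in the background but absent from the subset
for (g in sample(setdiff(genes, subset), 1800)) {
  ann[[g]] <- c(ann[[g]], "GO:0006412")  # translation
}
ann <- ann[lengths(ann) > 0]
subset <- intersect(subset, names(ann))

res <- enrich_terms(subset, ann, alpha = 0.05)
write.table(res, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- res[res$significant, ]
cat(sprintf("%d terms tested; %d significant after Bonferroni (alpha 0.05)\n",
            nrow(res), nrow(sig)))
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  %s: %s-represented, %d/%d subset vs %d/%d rest, p_bonf = %.3g\n",
              sig$term[i], sig$direction[i], sig$a[i], sig$a[i] + sig$b[i],
              sig$c[i], sig$c[i] + sig$d[i], sig$p_bonferroni[i]))
}
cat("Wrote results/enrichment.tsv\n")
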