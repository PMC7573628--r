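#!/usr/bin/env Rscript
# Stage 1: generate every synthetic dataset the downstream analyses use,
# with ground truth saved alongside. All randomness flows from one master
# seed through per-stage substreams, so any stage can be regenerated alone.

suppressPackageStartupMessages(library(plastburst))

master_seed <- 20260930
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tree <- species_tree_11()
write_newick(tree, file.path(out, "species_tree.nwk"))
cat("Species tree: 11 angiosperm taxa, root age",
    max(ape::node.depth.edgelength(tree)), "Myr\n")

## gene-family counts under the gain-death process ---------------------------
sim_fam <- sim_family_counts(tree, gamma = 0.001, delta = 0.002,
                             n_families = 2000, seed = substream(master_seed, 1))
write_counts_table(sim_fam$counts, file.path(out, "family_counts.tsv"))
cat(sprintf("Simulated %d families (gamma 0.001, delta 0.002 per Myr); %d are empty\n",
            nrow(sim_fam$counts), sum(rowSums(sim_fam$counts) == 0)))

## codon pairs at a planted synonymous divergence ----------------------------
ds_true <- 0.5
t_true <- t_for_ds(ds_true, kappa = 2, omega = 0.2)
dir.create(file.path(out, "codon_pairs"), showWarnings = FALSE)
for (i in 1:100) {
  sim <- sim_codon_pair(500, t_true, kappa = 2, omega = 0.2,
                        seed = substream(master_seed, 100 + i))
  writeLines(c(">seq1", sim$pair[1], ">seq2", sim$pair[2]),
             file.path(out, "codon_pairs", sprintf("pair%03d.fa", i)))
}
cat(sprintf("Simulated 100 codon pairs of 500 codons at true dS = %.2f (t = %.4f)\n",
            ds_true, t_true))

# (duplication trees with Ks matrices are regenerated from their seeds in
# stage 03 rather than cached)

## Ks mixture at the study's three peak positions ----------------------------
mix <- sim_ks_mixture(c(0.15, 0.55, 0.30), c(0.17, 1.62, 2.53),
                      c(0.05, 0.30, 0.30), 2000,
                      seed = substream(master_seed, 3))
write.table(data.frame(ks = mix$samples, component = mix$component),
            file.path(out, "ks_mixture.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("Simulated 2000 windowed Ks values (acceptance rate %.2f)\n",
            mix$truth$truth$acceptance_rate))

## nuclear genome with planted plastid insertions ----------------------------
nupt <- sim_nupt_genome(2e6, 30000, target_bp = round(0.047 * 2e6),
                        divergence = 0.03, seed = substream(master_seed, 4))
writeLines(c(">nuclear", nupt$nuclear), file.path(out, "nuclear.fa"))
writeLines(c(">plastid", nupt$plastid), file.path(out, "plastid.fa"))
write_truth_bed(nupt$truth, file.path(out, "nupt_truth.bed"))
cat(sprintf("Planted %d plastid insertions totalling %d bp (%.2f%% of 2 Mb)\n",
            nrow(nupt$truth$truth$bed), nupt$truth$truth$planted_bp,
            100 * nupt$truth$truth$planted_fraction))

cat("Done: inputs under", out, "\n")
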