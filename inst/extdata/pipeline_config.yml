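# Template run configuration for plastburst::run_pipeline().
# Every numeric default is the study setting it descends from:
#   - turnover: 5 optimiser restarts per model; evidence-ratio cutoff 2.7
#   - Ks: analysis window 0.05-5; clade-split threshold 5
#   - mixtures: up to 9 components; 1000 bootstrap replicates at alpha 0.01
#   - enrichment: Bonferroni-corrected Fisher tests at alpha 0.05
# Stages may either load real inputs (tree/counts/samples/hits paths) or
# carry a `sim:` block to run on seeded synthetic data.

seed: 1
out_dir: results/run1

stages:
  families:
    sim: {gamma: 0.001, delta: 0.002, n_families: 200}
    foreground: Mob          # terminal branch with its own gain/death rates
    restarts: 5
    evidence_ratio: 2.7
  ks_peaks:
    sim:
      lambda: [0.15, 0.55, 0.30]
      mu: [0.17, 1.62, 2.53]
      sigma: [0.05, 0.30, 0.30]
      n: 2000
    window: [0.05, 5]
    kmax: 9
    select: bic              # or "boot" for the sequential parametric LRT
    B: 1000
    alpha: 0.01
  nupt:
    sim: {genome_bp: 2000000, plastid_bp: 30000, target_bp: 94000,
          divergence: 0.03}
    min_identity: 90
    min_span: 2000
  # enrichment:
  #   subset: path/to/subset_genes.txt
  #   annotations: path/to/gene2go.tsv
  #   alpha: 0.05
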