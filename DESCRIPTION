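Package: plastburst
Title: Gene-Family Turnover, Ks Peak Detection and Nuclear Plastid DNA Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evolutionary-genomics toolkit for quantifying bursts of plastid
    DNA transfer into plant nuclear genomes and the gene-family dynamics that
    accompany them. Implements maximum-likelihood gain-death (immigration-death)
    models of gene-family size evolution on an ultrametric species tree with
    AIC evidence-ratio model selection; pairwise synonymous-substitution (Ks)
    estimation under a Goldman-Yang codon model with F3x4 frequencies plus an
    NG86 counting estimator; node-weighted Ks age distributions with recursive
    clade splitting; weighted Gaussian-mixture peak detection with BIC and
    parametric-bootstrap component selection; quantification of plastid DNA
    insertions from local-alignment hit tables with Circos-ready link output;
    GO-term enrichment by Fisher's exact test with Bonferroni correction; and
    seeded synthetic-data generators with machine-readable ground truth so the
    whole pipeline is testable without external genomes.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
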