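---
title: "Models and methods behind plastburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

plastburst quantifies two intertwined signals in a plant nuclear genome:
lineage-specific gene-family expansion/contraction on a dated species
tree, and the footprint of plastid-to-nucleus DNA transfer — both the raw
genomic fraction of nuclear plastid DNA (NUPTs) and the age structure of
duplicated genes read off synonymous-substitution (Ks) distributions.
This vignette explains the models, their assumptions, the tunable
parameters, and the choices made where the design was genuinely open.

## 1. Gene-family turnover: the gain–death model

Family sizes evolve on a rooted ultrametric species tree (branch lengths
in Myr) under an immigration–death process: new copies arrive at a gain
rate $\gamma$ per family per Myr, independent of current size, and each
existing copy dies independently at rate $\delta$ per copy per Myr. This
law has a closed-form transition: after time $t$, survivors of an initial
count $i$ are $\mathrm{Binomial}(i, e^{-\delta t})$ and gains are an
independent $\mathrm{Poisson}\!\left(\tfrac{\gamma}{\delta}(1 - e^{-\delta t})\right)$.
We chose this per-family gain (rather than per-copy birth) because it
matches the "gain and death" naming of the rate classes and admits the
closed form, which keeps the pruning likelihood out of matrix-exponential
territory; the truncated-generator matrix exponential is retained as an
independent oracle in the test suite, where the two agree to $10^{-10}$.

The likelihood of a family's leaf counts is computed by Felsenstein
pruning over the state space $\{0, \dots, \text{cap}\}$, with the cap
auto-raised to at least twice the largest observed count (doubling it
further changes log-likelihoods by $<10^{-8}$ in the tests). The root
count is marginalised under a prior; the default is the process's own
stationary distribution $\mathrm{Poisson}(\gamma/\delta)$ (truncated and
renormalised), with uniform and point-mass-at-zero priors selectable.
Nothing in the data identifies the root prior strongly, so it is kept
explicit rather than hidden.

Three branch-rate hypotheses are fitted by bounded multi-start ML in
log-rate space (bounds $10^{-8}$–$10$ per Myr, five starts drawn
log-uniform, deterministic given a seed): **global** (one $(\gamma,
\delta)$ pair), **branch** (separate rates on a designated foreground
terminal branch — the species of interest), and **free** (independent
rates per branch). Models nesting the global one are additionally
warm-started from a quick global fit so that extra freedom cannot lose
likelihood to an unlucky draw of starts. Model choice uses the Akaike
evidence ratio $\exp(\Delta\mathrm{AIC}/2)$ with cutoff 2.7 (a
$\Delta\mathrm{AIC}$ of about 2); the "2.7 times better" rule is stated
in the source methods without its arithmetic, and the evidence-ratio
reading is the one under which 2.7 corresponds to a conventional AIC
difference. Families observed in no species are unobservable in a real
orthogroup classification and are rejected as untestable; because of
that truncation, each family's likelihood is by default conditioned on
the family being observed in at least one species (dividing by
$1 - P(\text{all leaves zero})$). Without this ascertainment correction
the gain rate is overestimated by tens of percent on simulated data; with
it, recovery is unbiased to within Monte Carlo noise.

Significantly branch-rate families are classified by reconstructing the
maximum-posterior ancestral count at the foreground branch's parent
(inside–outside pruning under the fitted rates): **expanded** if the
foreground leaf count exceeds the reconstruction, **contracted** if
below, with a `lost_all` flag when the foreground count is zero against a
positive reconstruction. The classification rule is our design choice —
the upstream description gives none — and is deliberately the simplest
reconstruction-based reading of "expanded/contracted".

Under data simulated with global rates on the 11-taxon tree
($\gamma = 0.001$, $\delta = 0.002$ per Myr, 2,000 families), the joint
global fit recovers both rates within ±20%, and the per-family branch
test is conservative: well under 8% of families reach the 2.7 evidence
ratio.

## 2. Pairwise Ks estimation

Ks between two aligned coding sequences is estimated by ML under a
GY-style codon model: the generator over the 61 sense codons gives a
single-nucleotide change $i \to j$ rate $\pi_j$, multiplied by $\kappa$
for transitions and by $\omega$ for nonsynonymous changes;
multi-nucleotide changes have rate zero. Codon frequencies $\pi$ come
from F3×4: per-position nucleotide frequencies tallied from the pair,
multiplied per codon, stop codons removed and the rest renormalised.
Degenerate compositions (some sense codon at frequency zero) receive a
flat pseudocount of $0.5/61$ so the generator stays irreducible. The
generator is scaled to one expected substitution per codon per unit time,
and $(t, \kappa, \omega)$ are maximised with five log-uniform restarts
(bounds $t \in [10^{-4}, 30]$, $\kappa \in [0.1, 20]$,
$\omega \in [10^{-3}, 5]$); the transition matrix is computed by
eigendecomposition of the $\pi$-symmetrised generator, which is exact for
this reversible chain.

The dS convention follows Goldman–Yang: with $\rho_S$ the synonymous
fraction of substitution flux under the fitted $(\kappa, \omega)$ and
$f_S$ the same quantity at $\omega = 1$ (the mutational-opportunity site
fraction), $dS = t\,\rho_S / (3 f_S)$ and $dN = t(1-\rho_S)/(3(1-f_S))$.
External codon-ML programs differ in site-counting normalisation and the
source methods print no worked value to disambiguate, so exact numeric
agreement with any one program is not claimed; instead the simulator
computes true dS from the *same* flux decomposition of the generating
process, and the estimator must recover planted values (median within
±10% at dS = 0.5 over 100 pairs of 500 codons). Columns containing a
gap, ambiguity or stop in either sequence are dropped whole, mirroring
an alignment pipeline that skips insertions; estimates with $t$ at its
upper bound are flagged saturated.

NG86 counting (synonymous/nonsynonymous site counting with stop
mutations excluded, pathway-averaged differences, Jukes–Cantor
correction) is provided as a fast cross-check; its dS is undefined and
flagged when $p_S \ge 3/4$. The two routes agree within ~15% at moderate
divergence, and NG86 is verified against an independently written
enumeration oracle to $10^{-9}$.

## 3. Node-weighted Ks distributions

A family of $n$ genes yields $\binom{n}{2}$ pairwise Ks values but only
$n - 1$ duplication events, so raw pairwise distributions over-weight
large families. Following the node-weighting idea of Vanneste and
colleagues: each gene tree is midpoint rooted (if unrooted), polytomies
are resolved deterministically into zero-length binary nodes, and the
tree is split recursively from the root until every subclade's internal
pairwise Ks values are at most 5 — estimates beyond that are saturated
noise. Within a subclade, a duplication node whose child clades hold $a$
and $b$ leaves spans $m = a \cdot b$ cross pairs, and each cross-pair Ks
enters the distribution with weight $1/m$, so every duplication event
contributes unit mass. The weighting literature sometimes states $m$ as
"the number of duplication events"; only the cross-pair count satisfies
the sum-to-one property the procedure is defined by, so that is the
reading implemented. A missing cross-pair Ks (e.g. NG86 saturation) is
treated as above-threshold for splitting and skipped in weighting, with
the node's weights renormalised over its remaining pairs — conservative
in both roles. These invariants are enforced exactly: per-node weights
sum to 1, and the total weight of a distribution equals the number of
contributing duplication nodes.

## 4. Mixture modelling of Ks peaks

Whole-genome duplications leave coherent peaks in the Ks distribution of
retained duplicates. Samples are restricted to the window
$0.05 \le K_s \le 5$ (inclusive; below 0.05 sits the allelic/recent
pile-up, above 5 saturation) and fitted with univariate unequal-variance
Gaussian mixtures by weighted EM: responsibilities are multiplied by the
sample weights from the node-weighted distribution, and $n_\mathrm{eff} =
\sum w$ replaces $n$ in information criteria. With unit weights this is
exactly ordinary EM (tested bit-for-bit), and the fit agrees with an
independent mixture package on unweighted data. Whether the original
analysis fitted weighted or unweighted node-corrected values is not
stated; both modes exist here and weighted is the default for weighted
input. The printed EM control parameters in the source methods
(`maxit = 1e-30, maxrestarts = 1e-3, epsilon = 1e-10`) are internally
inconsistent as counts and are read as: convergence epsilon $10^{-10}$,
up to $10^4$ iterations, up to 1000 collapse-triggered restarts.
Initialisation is quantile-spaced means with pooled SD and equal
proportions; component collapse triggers a seeded perturbed restart.

The component count is selected two ways. By BIC (here in the
larger-is-better orientation $2\ln L - (3k - 1)\ln n_\mathrm{eff}$) over
$k = 1..9$; and by a sequential parametric bootstrap of the LRT: fit $k$
and $k+1$, simulate from the $k$-model, refit both on each replicate,
p-value = fraction of bootstrap LRTs at least the observed one, advancing
while $p \le 0.01$ (1000 replicates at full scale; the acceptance checks
run 200 to stay desk-sized, which only widens the p-value's Monte Carlo
noise). Confidence intervals around peak means are parametric-bootstrap
percentile intervals with components matched by sorted means; replicates
whose refit fails or collapses are discarded and counted. The CI method
behind the original figure is not described; the parametric bootstrap is
our choice and is validated by coverage on planted mixtures. On 2,000
samples planted at the three study peak positions (0.17 / 1.62 / 2.53,
proportions 0.15 / 0.55 / 0.30, SDs 0.05 / 0.30 / 0.30), BIC selects
$k = 3$ and the planted means fall inside their 95% CIs.

## 5. NUPT quantification

The NUPT scan consumes a 12-column tabular hit file (as produced by a
BLASTN run of the plastid genome against the nuclear assembly with
`-max_target_seqs 1000 -dust no -evalue 1e-5 -penalty -2 -word_size 9`).
The headline genome fraction is, by default, the plain sum of hit
alignment lengths divided by the assembly size — this is the arithmetic
under which the published mean insertion size equals total/n_hits, so
overlapping HSPs double-count; an interval-merged (union) total is
available behind `merge = TRUE` and is the mode used against planted
truth, since planted intervals are disjoint. "Insertion length" is the
hit's alignment-length column, gap columns included, matching the
consumed format. Scaffolds for the circular plot are those at least as
long as the plastid genome carrying a hit of ≥ 90% identity over
≥ 2000 bp, ordered by total aligned bp (the clockwise plotting order);
links are coloured by the Circoletto rule on percent identity,
$(score - \min)/(\max - \min)$ binned at 0.25/0.50/0.75 into
blue/green/orange/red, with a degenerate all-equal set drawn red.

For self-contained testing the package carries a deliberately small
ungapped seed-and-extend aligner (exact 9-mer seeds on both strands,
two-sided x-drop extension, per-diagonal merging, default minimum score
25 with match +1 / mismatch −2). It makes no claim to BLASTN's gapped
scoring or e-value statistics; on synthetic genomes with planted
insertions at ≤ 10% divergence it recovers planted bases nearly
completely, and on a 2 Mb genome with 4.7% planted plastid DNA the
merged recovered fraction lands within 0.3 percentage points of truth.

## 6. Enrichment

GO-term over/under-representation of a gene subset against the annotated
genome uses the two-sided Fisher exact test per term (every term
annotating at least one universe gene is tested, so depleted terms are
testable too) with Bonferroni correction at 0.05. The default universe
is the annotated genes only, mirroring denominators quoted in the source
annotation; a wider universe can be passed explicitly. Annotations are
used as given — no GO-graph ancestor propagation — because upstream
annotation pipelines already expand terms. Direction is reported from
the sample odds ratio with a Haldane 0.5 correction on zero cells
(reporting only; the test itself uses the raw table).

## 7. Synthetic data and what passing tests mean

Every stage has a seeded generator emulating its input regime: family
counts evolved branch-by-branch under the exact gain-death law;
codon pairs evolved from a stationary ancestor by the exact GY
transition matrix (truth dS from the generator's own flux
decomposition); windowed Gaussian-mixture Ks samples; coalescent-style
duplication trees whose pairwise Ks is twice the spanning node's age
plus Gaussian noise; nuclear genomes with planted, partially diverged,
optionally reverse-complemented plastid fragments at non-overlapping
positions, sizes lognormal ($\mu = \ln 200$, $\sigma = 1.2$ — a
right-skewed unimodal shape, chosen for qualitative realism, not as a
claim about the real insertion process). Generators are pure functions
of (parameters, seed); one master seed is split into per-stage
substreams by `substream(master, stage)` so stages regenerate
independently.

These simulations share the estimators' model assumptions by
construction. Passing recovery tests therefore demonstrates
correctness of the implementations and internal consistency of the
conventions (e.g. the dS definition), not robustness to real-data
violations: rate variation across families and sites, alignment error,
GC-biased gene conversion, assembly artefacts and repeat-induced
spurious hits are all outside what the synthetic module emulates.

The bundled 11-taxon tree (Moringa plus ten angiosperms) encodes the
published topology — Amborella sister to the rest, the magnoliid
avocado sister to monocots + eudicots — with round TimeTree-style
median ages chosen once (root at 173 Myr); it is a reconstruction for
analysis and simulation, not a dated phylogeny of record.

## 8. Problem sizes and numerical choices

Default analysis sizes were chosen once to keep the full suite
desk-scale: 2,000 families for rate recovery and test size; 100 pairs ×
500 codons for Ks recovery; 2,000 mixture samples with bootstrap sizes
200 (selection and CIs) against the full-scale 1000 used for real runs;
a 2 Mb genome with a 30 kb plastid for NUPT recovery; margins ≤ 30 for
exhaustive Fisher checks. Optimiser tolerances: L-BFGS-B on log-rates
(500 iterations) for turnover; Nelder–Mead with relative tolerance
$10^{-10}$ for the codon model; EM epsilon $10^{-10}$. Ties and
degenerate cases are resolved explicitly: AIC ties go to fewer
parameters, all-equal identity sets colour red, zero-frequency codons
get pseudocounts, saturated estimates are flagged and excluded from
weighting with renormalisation.
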