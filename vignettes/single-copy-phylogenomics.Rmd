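---
title: "Single-copy ortholog phylogenomics: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-copy ortholog phylogenomics: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Deep relationships in plant families that diversified tens of millions of
years ago are often unresolved by handfuls of chloroplast or ribosomal
markers.  Transcriptome sequencing changes the arithmetic: a single RNA-Seq
library yields thousands of protein-coding sequences per species, and a few
hundred single-copy nuclear genes concatenated into a supermatrix can
resolve a family backbone with essentially full support.  `scophylo`
implements that workflow end to end — from raw reads or assembled
transcripts through ortholog detection, supermatrix construction, tree
inference, a gene-subsampling stability protocol, molecular dating on
4-fold degenerate sites, and Ks-based screening for whole-genome
duplications — together with a seeded synthetic-data generator that
provides ground truth for every step.

The pipeline stages map onto the package's function groups:

1. **Preprocessing** — `filter_reads()`, `filter_contigs()`,
   `collapse_redundant()`, `extract_cds()`.
2. **Similarity** — `local_align_protein()`, `all_vs_all()`,
   `blast_all_vs_all()`, `read_similarity_table()`.
3. **Orthology** — `h_score()`, `build_graph()`, `cluster_families()`,
   `select_single_copy()`.
4. **Supermatrix** — `progressive_align()`, `backtranslate()`,
   `filter_genes_by_missing()`, `concatenate_alignments()`.
5. **Trees** — `nj_tree()`, `mp_search()`/`fitch_score()`, `ml_search()`/
   `gtr_loglik()`, `bootstrap_support()`, `rf_distance()`,
   `root_with_outgroup()`.
6. **Stability** — `gene_jackknife()`, `count_matching_gene_trees()`.
7. **Divergence** — `fourfold_sites()`, `strict_clock_date()`, `ks_pair()`,
   `ks_distribution()`.
8. **Synthetic data** — `simulate_species_tree()`,
   `simulate_gene_families()`, `simulate_codon_sequences()`,
   `degrade_and_emit()`, plus the bundled benchmarks
   (`simulate_benchmark()`, `simulate_stability_pool()`,
   `benchmark_species_tree()`).

# Ortholog detection: the H-score graph

All-vs-all protein similarity search produces raw alignment scores.  Raw
scores are length- and composition-dependent, so the pipeline normalises
each cross score by the larger of the two self scores:

$$H(G_1, G_2) = \frac{100 \cdot S(G_1, G_2)}{\max(S(G_1,G_1),\, S(G_2,G_2))}$$

An H-score of 100 means self-identity; unrelated genes score near 0.  Genes
become nodes in an undirected graph; an edge is added only when the aligned
span is strictly longer than one third of **both** genes (so domain-level
hits between multidomain proteins do not connect unrelated families) and
the H-score is strictly greater than 5.

Two conventions are deliberate:

* **Score symmetrisation.** Search tools report slightly different raw
  scores in the two directions of a pair.  The graph uses the maximum of
  the two, which makes the result independent of input order.  The
  coverage test uses the spans of the higher-scoring direction.
* **Strict inequalities** at both thresholds ("longer than 1/3", "larger
  than 5"), matching how the rules are stated wherever this family of
  pipelines is described.

Families are produced by constrained average-linkage agglomeration:
starting from singletons, the pair of clusters with the highest average
linkage (mean H over all cross pairs, absent edges counting 0) is merged,
and a merge is admissible only when the average linkage strictly exceeds 5
and — in the default `density_mode = "merge"` — the merged cluster's edge
density (realised edges over $k(k-1)/2$) strictly exceeds 1/3.  The
density rule could alternatively be read as a post-hoc family filter; both
are implemented (`density_mode = "post"` dissolves failing families), with
merge-time checking the default because it is the natural reading of a
constrained agglomeration and is deterministic.  Two-gene clusters have one
possible edge, so a pair with its edge present always satisfies the density
rule.  Equal-linkage ties are broken toward the lexicographically smallest
pair of cluster ids (a cluster's id being its smallest gene id), making
clustering reproducible regardless of input order.

One-to-one single-copy families — exactly one gene in every required taxon
— are the input to supermatrix construction.

For data-set sizes where the in-house aligner is impractical (thousands of
genes), `blast_all_vs_all()` drives the `blastp` binary and ingests its
13-column tabular output through `read_similarity_table()`, which preserves
E-value thresholding (default 1e-5) and enforces the presence of self-hits,
without which H-scores are undefined.

# Supermatrix construction

Each family's proteins are aligned by guide-tree progressive profile
alignment: a shared-k-mer distance (k = 3) feeds a neighbor-joining guide
tree, and profiles are merged by global affine-gap dynamic programming on
profile columns (BLOSUM62, gap open 11, extend 1; a gap of length L costs
`open + L*ext`).  With two sequences this is an optimal global pairwise
alignment, which is how the aligner is tested.  Iterative refinement of the
MUSCLE kind is out of scope; at within-family divergences (protein identity
typically 70–95% on the benchmarks) progressive alignment is adequate.

The aligned protein block is back-translated codon-by-codon, so the
nucleotide matrix is exactly three times the protein width — an invariant
asserted on every run.  The missing-data filter drops a gene when **any**
taxon exceeds 50% missing (gaps plus wholly absent rows; ambiguity
characters count as present, because the filter targets coverage rather
than polymorphism).  The "any taxon" quantifier and the threshold are both
exposed (`quantifier`, `max_missing_fraction`); averaging over taxa is the
alternative reading.  Retained genes are concatenated in lexicographic
family-id order with absent taxa gap-filled, and a partition table maps
each gene to its column ranges in both matrices.

# Tree inference

Likelihood calculations use GTR with a discrete Gamma(4) rate mixture.
Rate-category approximations of Gamma (CAT-style) are implementation speed
hacks; Gamma is their statistical target and is deterministic, so it is
what the package fits.  `gtr_loglik()` is an in-package Felsenstein pruning
implementation (patterns compressed, IUPAC ambiguities as partial
likelihoods) used directly by the dating MCMC and cross-checked in the
tests against closed forms and an independent implementation;
`ml_search()` delegates the heavy optimisation (branch lengths, model
parameters, NNI rearrangements from a neighbor-joining start on
Jukes-Cantor distances) to `phangorn`.  Branch lengths are bounded below at
1e-8; optimisation stops at a log-likelihood improvement below the
optimiser's default tolerance.

Parsimony uses an in-package Fitch engine (bitmask state sets; gaps as
wildcards) with random stepwise-addition starts and hill climbing.  All
equally-best distinct topologies are retained.  `swap = "tbr"` is
implemented as repeated subtree-pruning-regrafting proposals restarted from
each improvement — a documented simplification of full
tree-bisection-reconnection that loses little at 15-taxon scale, where the
NNI and SPR neighborhoods are already small.

Bootstrap support follows the *fast* bootstrap philosophy: sites are
resampled with replacement, each replicate starts from the full-data tree
and is refined by NNI only, with model parameters held at their full-data
estimates.  Support is the percentage of replicate trees containing each
internal bipartition of the full-data tree.

# The gene-jackknife stability protocol

The protocol quantifies how much gene sampling matters: for each gene
count N on a grid, draw a uniform random N-gene subset (without
replacement within a draw), concatenate, build a tree, and compare with the
reference topology (unrooted Robinson–Foulds distance 0 = match).  Draws
repeat until a match; the number of draws is the slot's
"repeats until match".  Thirty accepted trees per N are collected, each
with fast bootstrap supports.  Mean repeats fall toward 1 and mean support
rises toward 100 as N grows — the quantitative signature of signal
concentration in a concatenated data set.

Two implementation choices matter.  A per-slot attempt cap (default 1000)
with explicit censoring guarantees termination — without it, a reference
the data cannot produce would loop forever.  And the replicate tree builder
is configurable: full GTR+Gamma ML (`"ml"`), an NJ-started NNI-refined
Jukes-Cantor ML (`"fastml"`, the default), or plain distance NJ (`"nj"`).
The bootstrap inside each slot defaults to the distance builder, which is
cheap enough to run at every slot.

# Dating on 4-fold degenerate sites

A codon column enters the dating matrix only when, in **every** taxon, the
codon is ungapped, unambiguous and belongs to a 4-fold degenerate family
(CTx, GTx, TCx, CCx, ACx, GCx, CGx, GGx).  This strict intersection
guarantees the third position is synonymous along the entire tree, which is
the justification for treating the sites as approximately neutral.

`strict_clock_date()` samples internal node ages and a single clock rate by
Metropolis–Hastings.  The likelihood is the pruning likelihood of the 4D
matrix with branch lengths `rate × duration`; the prior is normal on
calibrated nodes (e.g. a stem calibration of 58.5 ± 5.0 Ma or a root
calibration of 90.7 ± 1.0 Ma, both expressible via the `clade`/`type`
columns of the calibration table), uniform-within-constraints on other
ages, and diffuse lognormal on the rate (meanlog log(0.002), sdlog 2, in
substitutions/site/Ma).  Node ages move by sliding windows reflected into
the (oldest child, parent) interval — symmetric, so no Hastings correction —
and the rate by a multiplicative scale move.  Proposal scales adapt toward
roughly 30% acceptance during burn-in (Robbins–Monro style) and are then
frozen, so the kept samples come from a fixed kernel.  A strict clock, not
a relaxed one, is the deliberate scope: a single rate is identifiable from
4D sites plus calibrations, is adequate for parameter-recovery testing, and
avoids the prior-sensitivity of rate-autocorrelation models.  With zero
data the sampler reproduces its priors, which is asserted in the tests.

Stem versus crown calibration semantics are explicit: `type = "crown"`
attaches the prior to the clade's MRCA, `type = "stem"` to that node's
parent.

# Ks screening for whole-genome duplications

`ks_pair()` implements the 1986 Nei–Gojobori estimator: synonymous site
counts per codon from degeneracy (changes to stop codons counted as
nonsynonymous, site fractions renormalised to 3 per codon), difference
counts averaged over equally-weighted mutational pathways (pathways passing
through stop codons are excluded unless every pathway is blocked), sites
averaged over the two sequences, and the Jukes–Cantor correction
$K_s = -\tfrac34 \ln(1 - \tfrac43 p_S)$.  Pairs with $p_S \ge 3/4$ are
flagged saturated rather than given an arbitrary large value.  Codon pairs
containing gaps or ambiguity characters are dropped pairwise.
Length-mismatched pairs are aligned through their protein translations
first.  `ks_distribution()` applies this to every within-taxon paralog pair
implied by the gene families and bins the values; a concentration of pairs
at a common Ks is the classic footprint of a shared whole-genome
duplication.

NG86 assumes no transition/transversion bias; under a transition-biased
mutation process it overestimates Ks by mis-partitioning sites (about +8%
at Ks = 1 with a 2:1 bias on the benchmark).  The estimator-consistency
tests therefore simulate under the unbiased model — the regime the
estimator is defined for — while the WGD-peak test runs under the
transition-biased default to show the peak survives realistic bias.

# The synthetic-data generator

The generator is first-class, tested code; every pipeline claim is
validated against its truth records.

* **Species trees** are pure-birth (Yule) trees conditioned on the taxon
  count and rescaled to a root age (default 100 time units, read as Ma).
  Shape is irrelevant to the correctness tests, so the simplest ultrametric
  generator is used.
* **Gene families** evolve inside the species tree as a linear birth–death
  process of duplication (default 5e-4 per lineage per Ma) and loss
  (1.5e-4).  On the 15-taxon benchmarks this yields roughly 60–70%
  strictly single-copy families — so that ortholog detection is tested on
  a data set where about a third of the families are decoys.
* **Codon sequences** evolve on a 61-state stop-free mutation-level codon
  model: GTR nucleotide exchangeabilities (default transition bias 2),
  position-independent base frequencies, and a nonsynonymous scaling
  `omega` (default 0.2, moderate purifying selection).  Stop codons are
  excluded from the state space, so translation is always defined; the
  matrix is scaled so one branch-length unit is one expected nucleotide
  substitution per site at stationarity.  The stationary distribution is
  the product measure restricted to sense codons, so its nucleotide
  marginals differ slightly from the input frequencies;
  `codon_stationary()` gives the exact values, and the long-branch
  law-of-large-numbers test checks against them.  The default rate is
  0.002 substitutions/site/Ma, a plant-nuclear-like value; per-gene rate
  multipliers are lognormal (sdlog 0.3).
* **Degradation** truncates transcripts by a stated fraction from a random
  end, and samples 90 bp paired-end reads with Phred+33 qualities
  (configurable to Phred+64), a low-quality-base rate and an N rate.  The
  truth map records exactly what was removed, so the downstream
  missing-data filter can be scored against it.
* **Gene-tree discordance** is produced by age-compatible NNI moves on the
  dated species tree (`perturb_tree_nni()`), a cheap stand-in for
  incomplete lineage sorting that preserves ultrametricity.
* An optional **whole-genome duplication** duplicates every lineage alive
  at a stated age with a stated retention probability, giving dated paralog
  pairs for the Ks benchmarks; an optional codon-level deletion process
  (geometric lengths) provides alignment stress.

What the generator does **not** emulate: realistic Illumina error and
coverage profiles, expression-level variation of non-normalised libraries,
alternative splicing, true coalescent gene-tree distributions, insertions,
GC-content heterogeneity across lineages, and assembly chimeras.  Passing
the benchmarks therefore demonstrates correctness of the pipeline's logic
under its stated models — not robustness to every artifact of real
transcriptome data.

# Benchmark design and problem sizes

The validation benchmarks are fixed designs, chosen once:

* **Ortholog recovery**: 15 taxa × 300 families × 200 codons,
  duplication/loss as above; similarity via `blastp` at E ≤ 1e-5.  Scored
  as the fraction of truly single-copy families recovered with exactly
  their true membership, and the number of families mixing two true
  families (chimeras).
* **Topology recovery**: the fixed dated tree `benchmark_species_tree()` —
  root 90 Ma, five clades, two 1.5 Ma internal edges mimicking a rapid
  radiation — with 30–40 single-copy genes of 300 codons.  A fixed tree is
  used because random Yule shapes can contain arbitrarily short internal
  edges that no method could resolve, which would test the tree draw, not
  the pipeline.
* **Stability**: a 70-gene pool of 100-codon genes on the same tree, 40%
  of genes on 2-NNI-perturbed topologies.  These sizes put 10-gene
  subsamples at roughly a 70% match rate against the reference — the
  regime where "repeats until match" is informative — while 60-gene
  subsamples always match.  The grid runs N = 10..60 by 10 with 30 slots
  per N.
* **Dating**: 8-taxon trees, ten 200-codon genes (a few hundred 4D sites),
  true-age root calibration (sd 2 Ma), 8000 MCMC steps with 2000 burn-in;
  20 seeded replicates for the coverage check.  The prior-recovery check
  uses a 90.7 ± 1.0 Ma root calibration with no data.
* **Ks**: 10 kb CDS pairs at true dS 0.1/0.5/1.0 (truth defined from the
  generator's rate matrix via `codon_ds_per_unit()`), and a WGD at the age
  corresponding to paralog dS = 1.

# Numerical choices and degenerate inputs

* Strict boundaries throughout the filters: a 90 bp read with exactly 40
  low-quality bases or exactly 20% N survives; a 150 bp contig survives; a
  taxon with exactly 50% missing data survives; an aligned span of exactly
  one third, or an H-score of exactly 5, does not make an edge.
* Negative NJ branch lengths are clamped to zero with the deficit moved to
  the sister edge.
* JC distance corrections are capped just below saturation (p = 0.745) to
  stay finite on extreme bootstrap resamples.
* The Fitch engine treats `- ? N X` as wildcards; the likelihood engine
  maps IUPAC codes to partial likelihoods.
* Coordinates are 0-based half-open internally and 1-based inclusive in
  every written report (CDS tables, partition files).
* Empty inputs return empty outputs (contig filter, Ks histograms); a
  single sequence passed to the aligner returns unchanged; an unreachable
  jackknife reference censors at the attempt cap rather than looping.

# Limitations

* Bayesian mixture-model tree inference and relaxed-clock dating are out of
  scope; the dating module is a strict-clock sampler, not a reimplementation
  of mcmctree.
* De novo assembly is external: the pipeline starts from reads only for
  filtering, and from transcripts for everything downstream.
* The parsimony TBR is an SPR-based approximation; exhaustive TBR adds
  little at the tree sizes targeted here but matters for hundreds of taxa.
* Heuristic seeding for large-scale in-house similarity search is not
  implemented; beyond a few hundred proteins, use the `blastp` wrapper.
* Real-data headline numbers (hundreds of orthologs from sixteen
  transcriptomes, specific node ages) depend on deposited read archives and
  an external assembler and are not reproduced here; the package validates
  the method's behaviour on synthetic data with known truth.
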