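---
title: "Models and methods behind the allerscan pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the allerscan pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models, algorithmic choices and
tunable parameters behind each stage of the package, and what the
synthetic-cohort generator does and does not emulate. It is the place to
look when a default needs justifying or changing.

## The assay in brief

Phage immunoprecipitation sequencing (PhIP-Seq) displays a library of
peptide tiles — here, tiles spanning allergen proteins — on T7 phage.
Serum antibodies (IgE captured on anti-IgE beads, IgG on protein A/G)
pull down the phage they recognise; sequencing the peptide-encoding
inserts and counting reads per clone turns antibody binding into a
clones × samples count matrix. Everything downstream is a question
about which counts are larger than the no-serum ("mock")
immunoprecipitations can explain.

## Library design

`tile_proteins()` slices each protein into 56-residue windows advancing
by 28 residues, so consecutive tiles overlap by 28. The tail of a
protein rarely lands on a window boundary; the final tile is anchored to
the C-terminus (start = L − 56), accepting a larger overlap for the last
pair, so that every residue is covered by at least one tile. Proteins
shorter than one tile yield a single full-length tile — padding
characters would not be translatable peptide content. Tile counts
therefore equal `1 + ceiling((L - 56) / 28)` for L ≥ 56. Coordinates
are 0-based half-open internally; clone ids are `proteinID_start_end`.

`reverse_translate()` maps each residue to the highest-ranked codon of a
packaged E. coli usage table. Production-scale libraries are synthesised
and cloned, so the insert must avoid the cloning enzymes' recognition
sites: when a forbidden motif (defaults: EcoRI `GAATTC`, HindIII
`AAGCTT`) appears, the codon at the leftmost position overlapping the
motif is bumped to its next-ranked alternative and the scan restarts
from the 5′ end. The procedure is deterministic, and an unresolvable
conflict (all overlapping codons exhausted) is an error naming the tile.
Duplicate tiles arising from homologous proteins are retained as
distinct clones; collapsing near-identical proteins is an upstream
database step this package does not perform.

## The synthetic cohort generator

`simulate_cohort()` exists so that every analysis stage can be tested
against known ground truth. It emulates:

* **Library representation** — clone proportions are log-normal with
  log10-scale SD `abundance_sigma` (default 0.5, chosen so that about
  68% of detected clones fall inside the symmetric one-log window used
  by `library_qc()`, since 2Φ(0.5/σ) − 1 = 0.68 at σ = 0.5), and an
  exact `dropout_fraction` (default 0.042, i.e. ~95.8% of clones
  detectable) is absent entirely.
* **Counting noise** — counts are negative binomial with variance
  μ + φμ²; one global φ (default 0.02, calibrated so technical
  replicates at depth 10⁶ reach log-scale R² ≈ 0.99, the reproducibility
  regime of a well-behaved IP assay; φ = 0 degenerates to Poisson).
  Enrichment redistributes read share competitively: fold changes
  multiply proportions which are then renormalised, so unenriched
  clones are slightly depleted in strongly reactive samples, as in real
  sequencing.
* **Group structure** — each group specification plants a per-sample
  reactive set (organism, set size, log-normal fold-change
  distribution) per isotype. Defaults describe a wheat-allergy study:
  32 allergic samples with broad strong wheat IgE and IgG, 27
  sensitized with narrow IgE but intermediate IgG, 27 non-allergic with
  essentially none.
* **A discriminator epitope** — three near-identical 56-residue
  "purothionin-like" isoform proteins share a conserved core, so their
  tiles form one 3-node component of the homology graph. The family is
  planted IgG-reactive at rate 0.7 in sensitized and non-allergic
  samples and IgE-reactive in 28% of allergic samples, mirroring an
  epitope whose isotype split separates allergy from tolerance.
* **Longitudinal therapy effects** — treated subjects get a paired
  second timepoint: a fraction (default 0.5) of their IgE-reactive
  peptides is cleared, new IgG-reactive wheat peptides are gained, and
  (at rate 0.85) the epitope family becomes IgG reactive.
* **Technical replicates** — shared planted fold changes, independent
  counting noise.

The generator does **not** emulate sequencing errors, PCR amplification
bias, barcode hopping, batch effects, cross-reactive antibody binding
to merely similar peptides, or clinical covariates. Passing tests on
this simulator therefore demonstrate that the statistics recover what
was planted under the stated noise model, not that the defaults equal
any particular study's latent parameters. A single integer seed
determines every draw; ground truth is exported alongside the data and
no analysis function reads it.

## Mock-IP null model and enrichment test

`fit_mock_model()` estimates each clone's expected read share from the
mocks as regularised pooled counts, `p̂ = (Σ c + α) / Σ(Σ c + α)` with
α = 0.5; α = 0 is allowed, in which case clones unseen in mocks carry
p̂ = 0 and are later tested against the minimum positive proportion and
flagged. Dispersion is estimated per clone by method of moments on
depth-normalised mock counts (φ = (s² − m)/m², clamped at 0), then
shrunk toward a trend — the mean positive estimate within log-mean
bins — with weight `shrinkage_strength` (default 0.5, an even
compromise between per-clone estimates that are noisy with few mocks
and a trend that ignores genuine clone-level variation). With a single
mock no variance exists; a loud warning is raised and a fallback
dispersion (default 0.2, deliberately conservative) is used everywhere.

`test_sample()` compares each observed count to NB(μ = depth · p̂, φ).
The p-value is the one-sided upper tail P(X ≥ count), computed with R's
exact negative binomial distribution function (Poisson when φ = 0); a
count of 0 always gives p = 1, and values are clamped into (0, 1]
against underflow. Only enrichment is tested — depletion is not a
"hit" in this assay. Fold change is `(count + 1) / (μ + 1)`; the
pseudocount stabilises clones with tiny expectations. Depth
normalisation is by total sample counts; no trimmed-mean factors are
applied, since mocks and samples come from the same library.

`call_hits()` applies the three thresholds jointly: count ≥ 100,
p ≤ 0.001 and fold change ≥ 5 (the threshold trio standard for this
assay; "p of at least 0.001" is read in the significance direction,
p ≤ 0.001). No multiple-testing correction enters hit calling — the
fixed p threshold is deliberately part of the definition — but a BH-FDR
column is emitted for users who want one. The hits matrix stores the
fold change for hits and exactly 1 for everything else, so downstream
log-scale analyses see non-hits as "no signal" rather than as missing.

## Homology graph and repertoire breadth

Repetitive storage proteins make raw hit counts a poor measure of how
many distinct specificities a serum contains: one antibody binding a
repeated epitope can light up dozens of tiles. `build_homology_graph()`
links two peptides when they share an identical substring of length
k = 7 — a minimal linear-epitope length; sharing any ≥7-mer is
equivalent to sharing a 7-mer, so edges are found with a 7-mer index in
near-linear time rather than all-pairs alignment.

`breadth()` reports the size of a *maximal independent vertex set* of a
sample's reactive peptides: repeatedly take the lowest-degree remaining
reactive node (ties broken lexicographically by id, which makes the
result deterministic), add it, and delete it with its neighbours. The
construction guarantees independence (members share no homology) and
maximality (every excluded reactive peptide is adjacent to a member).
Maximal is not maximum: the greedy set can be smaller than the largest
independent set, and the tests compare it against the exact optimum on
small graphs as a logged statistic, not a requirement. Note one
documented non-property: deleting edges does not monotonically increase
greedy breadth, because the tie-break order changes; the reliable
bounds are breadth ≤ |reactive set|, with equality exactly when the set
is already independent. Breadth is computed per sample per isotype on
an organism-filtered reactive set (all of a sample's hit wheat
peptides, by default unfiltered by prevalence).

`epitope_clusters()` returns connected components of the reactive
subgraph (size ≥ 2, sorted by size then first member; singletons listed
separately), and `consensus_motif()` anchors a cluster on its most
frequent shared k-mer (lexicographic tie-break) to produce a
position-frequency matrix; if no k-mer spans all members, the largest
anchorable subset is used with a warning.

## Cohort statistics

* **Filters** (applied in this order): peptides recognised by ≥ 3
  samples; then organisms contributing ≥ 5 recognised peptides. Both
  boundaries are inclusive and the filters are idempotent.
* **Clustering** — binary mode uses the base-R binary distance
  (Jaccard complement on hit indicators); value mode uses Euclidean
  distance on log10 hit fold changes; both agglomerate with Ward.D2,
  which is deterministic for a fixed input ordering.
* **Group comparisons** — two-sided Wilcoxon rank-sum via
  `stats::wilcox.test`, exact whenever sample sizes permit and no ties
  are present; no multiple-testing correction by default (a BH column
  is optional). Paired analyses use the two-sided signed-rank test;
  zero differences are dropped (Wilcoxon's original treatment), and an
  all-zero comparison is reported as degenerate with p = 1 rather than
  an error.
* **Isotype concordance** — reactive peptide × sample pairs (union of
  IgE and IgG hits over matched samples) are partitioned into both /
  IgE-only / IgG-only; the fractions sum to 1 whenever any reactive
  entry exists.
* **Epitope summaries** — a named epitope is a peptide set (the three
  isoform tiles, for the discriminator family); per-sample reactivity
  aggregates members by maximum hit fold change, and group prevalence
  is the fraction of samples with any member hit.
* **Therapy response** — a responder gains strictly more than 1000 mg
  of tolerated challenge dose between baseline and post-treatment;
  missing doses yield "not evaluable" (`NA`), not an error.

## Numerical and degenerate-input choices

Tail probabilities are clamped to `[.Machine$double.xmin, 1]`;
dispersions below 1e-12 are treated as Poisson. `replicate_r2()` uses
log10(count + 1) and flags zero-variance inputs as undefined rather
than returning a spurious number. Strict integer parsing on count
input names the first offending row and column. The read mapper
verifies insert-prefix uniqueness at the configured match length
(default 50 nt) before counting, so exact-match assignment is
unambiguous by construction; reads differing by even one base are
deliberately unmapped.

## Problem sizes used by the test suite

The suite exercises the pipeline at the scales the methods target:
hit-calling calibration on 19,000-clone libraries at depth 10⁶ with 8
mocks over 20 seeded runs; a full default cohort (~500 clones, 224
samples including mocks, replicates and paired timepoints); 500 random
graphs of up to 20 nodes against the exact maximum-independent-set
oracle; exhaustive pairwise 7-mer checking on 100 random peptides; and
full enumeration of both rank tests for all group sizes up to 8. These
sizes were chosen as the smallest that still separate correct from
subtly wrong behaviour at each stage.

## Known limitations

The homology criterion (shared 7-mer) is a proxy for antibody
cross-reactivity; it misses similarity without identity (an optional
alignment-score criterion would catch conservative substitutions, and
k is configurable). The dispersion trend is a binned mean rather than
a smooth fit, which is robust but coarse for very small libraries. The
simulator's group structure is deliberately simple — disjointly drawn
reactive sets with log-normal effects — so estimates of, say, isotype
concordance on simulated data reflect that construction, not biology.
Whether fold change should be computed against mock expectation or
library input abundance is a genuine modelling choice; the mock-null
framing is the default here because the test statistic is defined
against the same null.
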