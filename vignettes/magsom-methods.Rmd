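---
title: "Methods: composition-based genome binning and sulfide-oxidation energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition-based genome binning and sulfide-oxidation energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magsom)
```

## Scope and scientific setting

Sulfidic cave streams host dense chemolithoautotrophic biofilms in which
filamentous Epsilonproteobacteria (notably *Sulfurovum*- and
*Sulfuricurvum*-like populations) oxidize dissolved sulfide using oxygen or
nitrate, leaving elemental sulfur, S(0), as a conspicuous solid phase when
electron acceptors are scarce. Metagenomic study of such communities rests
on a chain of computations: assembled contigs are binned into draft genomes
by nucleotide composition, bins are curated by gene taxonomy, GC and
coverage, bin quality is summarised by assembly statistics and
marker-gene completeness, functional genes are tallied under explicit
homology-score thresholds, and the competing sulfide-oxidation reactions
are compared thermodynamically. magsom implements that chain as a tested,
seedable pipeline, together with a synthetic community generator that
provides ground truth for every stage. Sequencing, assembly, read mapping,
homology search and phylogenetics are out of scope: the package starts from
contigs, gene calls and best-hit tables.

## Tetranucleotide profiles

Each contig of at least 2,500 bp is cut into consecutive windows of 5,000
bp; a terminal remainder of at least 2,500 bp stands alone, a shorter one
is merged into the preceding window. The 2,500 bp floor mirrors standard
practice for composition-based binning: below that length 4-mer
frequencies are too noisy to place reliably. Each window contributes a
vector of relative tetranucleotide frequencies. Because the strand of an
assembled contig is arbitrary, a 4-mer and its reverse complement are
pooled under one canonical key by default, giving 136 features (16 of the
256 tetramers are their own reverse complement). Windows containing
ambiguous bases simply skip the affected 4-mers — nothing is imputed — and
GC content excludes ambiguous bases from numerator and denominator,
returning `NA` (never 0) for an all-N sequence. Frequencies, not z-scored
counts, are the feature; per-column standardization is available behind
`standardize = TRUE` for diagnostics.

## The emergent self-organizing map

Window vectors are embedded with a classical online SOM on a toroidal
grid: each presented sample pulls its best-matching unit (BMU) and, under
a Gaussian neighborhood of exponentially decaying radius and rate, the
surrounding nodes toward itself. Defaults: 20 epochs, radius from half the
smaller grid dimension down to 1, learning rate 0.5 down to 0.05, toroidal
topology. Weights are initialized uniformly at random inside the
per-feature data range, and the mean quantization error is recorded at
every epoch boundary so the contraction of the map can be audited
(`glance()` on the fit).

Two choices depart from the smallest-possible-map tradition and deserve
explanation:

* **Grid size ~ 2 n.** An *emergent* map needs substantially more nodes
  than samples so that clusters appear as basins separated by U-matrix
  ridges rather than as single prototype nodes. With the common
  `5 * sqrt(n)` sizing the map degenerates into a vector quantizer: on the
  default synthetic community the segmentation then flickered between four
  and five genomes depending on the (seeded) presentation schedule. At
  two nodes per sample (capped at 4,000 nodes, floor 10 x 16, golden-ratio
  aspect) the five genomes separate robustly across seeds and across a
  wide band of segmentation thresholds.
* **Canonical presentation order.** The per-epoch seeded shuffle indexes a
  canonical ordering of the samples by their content, not their input row
  position. Training is therefore *exactly* invariant to row permutation
  of the input matrix — permuted inputs yield identical final weights —
  which is verified in the test suite via an adjusted-Rand-index of 1
  between permuted runs.

BMU lookup breaks distance ties toward the lexicographically smallest
(row, column) node, and the row-major storage of weights makes that
tie-break a by-product of `which.min`.

## Automated map segmentation

The original interactive workflow drew bin boundaries on the U-matrix by
hand. magsom replaces this with a deterministic rule: compute each node's
mean distance to its (8-connected, toroidal) neighbors — the U-matrix —
remove every node whose U-value exceeds a threshold quantile (computed
over all map nodes), split the surviving subgraph into connected
components, and let each window inherit the component of its BMU. A
threshold quantile of 1 removes nothing, and the torus being connected,
yields a single bin — a useful degenerate check.

The default quantile is 0.5: with the map sized at roughly twice the
sample count, data-bearing basins occupy about half the nodes, so
retaining the lower half of the U-distribution keeps basins and cuts
ridges. (At 0.6 the retained set consistently included a low-ridge
corridor between the two most similar genomes of the default fixture,
merging them.) Windows whose BMU sits on the removed ridge are assigned to
the component of the nearest retained node in weight space by default
(`unassigned = "nearest"`); the strict rule that leaves them unassigned is
available (`"drop"`), but it orphans roughly a third of the windows —
enough to make downstream completeness unattainable. A contig takes the
majority bin of its windows; ties leave it unassigned.

Recovery is scored as the adjusted Rand index (ARI) between contig-level
bins and the ground-truth contig-to-genome map, computed over assigned
contigs; an independent k-means oracle (same matrix, true k) must agree
with the map segmentation at ARI >= 0.9 on separable instances.

## Bin curation and quality statistics

Curation chains two rules, in the order they would be applied at the
bench:

1. **Taxonomic majority vote.** A scaffold stays in a bin only if strictly
   more than 50% of its genes have best hits to the bin's taxon at the
   chosen rank; exactly half fails. Scaffolds without genes cannot be
   voted on and are dropped with an explicit `no_genes` flag. In the
   pipeline the vote target of each bin is its own plurality gene taxon,
   so curation is meaningful for every bin, not only the focal one.
2. **GC/coverage filtering.** A contig is kept if its GC lies within 5
   percentage points (absolute, default) of the bin median and its depth
   within a multiplicative 3x band around the bin median. The bands are
   deliberately generous — they are meant to kill gross contaminants
   (foreign GC, multi-fold depth) without nibbling at the genuine
   within-genome spread. Bins of fewer than three contigs have no usable
   median and pass through with a warning.

Assembly statistics follow the standard definitions; N50 is the length of
the shortest contig in the minimal descending prefix reaching half the
total. Completeness is the percentage of a reference single-copy marker
set seen at least once among the bin's genes; duplicates are counted but
can never raise completeness. The shipped default marker set is a
synthetic stand-in: 19 universal ribosomal proteins, matching the size of
marker sets typically used for draft-genome completeness — the statistic
depends only on set size and membership, and the set is an argument
everywhere. Competing reassemblies are ranked on longest contig
(descending), N50 (descending) and scaffold count (ascending); the
minimal rank-sum wins, ties broken by N50 then input order.

## Hit filtering and abundance

Two score profiles coexist deliberately, as both are in common use:

* whole-metagenome class assignment: e-value < 1e-4 (strict) AND query
  coverage >= 0.75 (inclusive), else "unassigned";
* functional-gene quantification: e-value <= 1e-4 AND coverage > 0.70
  (strict) AND bit score > 100 (strict).

Abundance is normalized to hits per kilobase of gene per million reads:
`count / ((length/1000) * (reads/1e6))`. Reconstructed 16S abundance
estimates below 0.01% are removed; survivors are *not* renormalized by
default (the analysis proceeds on filtered values), with renormalization
behind a flag. "Best hit" means the top bit score per query, ties broken
by lower e-value, then input order.

## Reaction energetics

Reactions are signed stoichiometric vectors over a thermodynamic table of
aqueous-standard-state free energies of formation (kJ/mol, 25 °C;
elements in reference state at zero). The default table — H2S −27.9,
SO4^2− −744.6, NO3− −111.3, NO2− −37.2, NH4+ −79.4, H2O −237.2 — is a
standard literature compilation and is an explicit, swappable input.

`balance_check()` reports per-element and charge residuals. Several
published sulfide-oxidation stoichiometries are not balanced as typeset
(one even emits H2 with no oxygen sink); `rebalance()` therefore solves
the element + charge linear system over the reaction's species augmented
with free H2O and H+, holding the electron-donor coefficient at 1. The
system is solved with a Moore–Penrose pseudoinverse, so an
underdetermined case returns the minimal-norm stoichiometry and an
inconsistent one fails with a rank report; coefficients below 1e-8 are
dropped as zero.

`delta_g_prime()` applies the biochemical convention: deltaG0' = deltaG0 +
nu_H+ * (−RT ln10 * pH), with all species other than the proton at unit
activity and T fixed at 298.15 K (−39.96 kJ/mol per product proton at pH
7). Temperature extrapolation and activity corrections are out of scope.
Under the default table the eight-reaction table reproduces the published
values for the balanced/rebalanced equations within ~1%, and in every
acceptor pairing complete oxidation to sulfate is more exergonic than
incomplete oxidation to S(0) — the energetic argument for why
electron-acceptor limitation favors S(0) accumulation.

## The synthetic community generator

The generator emulates exactly the statistical structure the analyses
assume, nothing more:

* **Composition.** Each genome is an order-2 Markov chain whose transition
  rows are tilted toward a target GC and then perturbed per-genome by a
  lognormal factor (scale 0.15), giving genome-specific 4-mer signatures.
  After perturbation a bisection on a G/C column multiplier pins the
  chain's *stationary* GC to the target, so realized GC converges to the
  target as genomes grow — without the calibration the perturbation
  biases GC by up to a percentage point and convergence stalls.
* **Fragmentation and depth.** Lognormal fragment lengths (median 4 kb,
  sdlog 0.35) walked along the genome; fragments under the 2.5 kb floor
  become gaps, so contigs jointly cover at most 100% of the genome.
  Per-contig depth is the genome abundance times lognormal noise (sdlog
  0.25), exercising the coverage filter.
* **Genes, markers, hits.** Genes are abstract non-overlapping intervals
  (~1 per kb; length ~80% of spacing, exponential gaps), not translated
  ORFs — downstream rules consume only coordinates, labels and scores.
  Each of the 19 markers is placed once per genome; markers are lost
  naturally when their gene straddles a fragment boundary. Hit tables
  draw e-values, bit scores and coverages from configurable generators,
  and mislabel a controlled fraction of genes with a taxon from the rest
  of the community.

The default community has five genomes — three Epsilonproteobacteria
(two *Sulfurovum*-like at GC 0.34 and 0.41, one *Sulfuricurvum*-like at
0.47) and two non-target genomes (0.55, 0.62) — of 300 kb each at
abundances 15/8/5/3/2, fragmenting into ~325 contigs (~1.4 Mb) under seed
42, with a 10% taxon mislabeling rate. The 300 kb genome length keeps the
fixture desk-scale; real genomes are 10x larger, but the binning signal
depends on window counts and compositional separation, not genome size.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: repeats and horizontally transferred regions
(composition outliers within a genome), strain mixtures, chimeric
contigs, sequencing error, uneven within-genome coverage, and real gene
annotation noise beyond uniform mislabeling. The GC spread of the default
community makes it honestly separable; a community of five genomes at
identical GC with subtler signature differences would be harder, and no
claim is made about such cases.

## Problem sizes and numerical checks

The test suite exercises: the full default fixture end-to-end (ARI,
marker capture >= 85%, contamination <= 5% by bp); 20-seed contaminated
bins (10% foreign bp at +0.15 GC and 4x depth: >= 90% contaminant bp
removed, <= 5% native bp lost, in 20-seed aggregate); 1,000-case
brute-force oracles for N50 and k-mer counting; 1,000-bin marker-dropout
simulations at p in {0, 0.05, 0.1} (mean completeness within one point of
100(1−p)); and GC convergence at genome lengths 5e4 / 2.5e5 / 1e6 (the
model's own minimum genome length is 50 kb). These sizes are the
package's chosen demonstration scale: large enough for the statistical
assertions, small enough to run comfortably on a laptop.

Degenerate inputs are handled explicitly rather than silently: empty
contig sets, all-N sequences, bins under three contigs, fragment
distributions that cannot reach the length floor, single-row training
matrices, unresolvable species, and unbalanced reactions all either
warn, return typed empties, or fail with the offending name.

## Known limitations

* The SOM is trained online in R; at the package's intended desk scale
  (hundreds to a few thousand windows) training takes seconds to a couple
  of minutes, but it is not engineered for million-window metagenomes.
* Segmentation has no notion of nested or adjacent clusters separated by
  ridges below the threshold quantile; genuinely overlapping composition
  clouds will merge.
* Completeness uses presence/absence of a marker set only; it is not a
  contamination estimator beyond the duplicate count.
* The thermodynamic layer is standard-state plus pH only — no ionic
  strength, temperature or speciation corrections — matching the level of
  the published comparison it reproduces.
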