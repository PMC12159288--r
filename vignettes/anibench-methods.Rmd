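---
title: "Benchmarking ANI estimators against tree distance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ANI estimators against tree distance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anibench)
```

## The benchmarking idea

Average nucleotide identity (ANI) has no single mathematical definition —
every tool operationalizes "identity over homologous regions" differently,
through fragment alignment, whole-genome anchoring, or k-mer sketching. What
all of them try to approximate is evolutionary distance. anibench therefore
scores an estimator by how well it *ranks* genome pairs: on a set of genomes
related by a known phylogeny, a good similarity estimator should decrease
monotonically with the patristic distance (sum of branch lengths) between two
leaves. The benchmark statistic is the tie-aware Spearman rank correlation
between the estimator column and the tree-distance column over all
N(N-1)/2 unordered pairs, reported together with a log10 p-value. A
similarity is expected to correlate *negatively* with tree distance.

Two points are worth stating plainly. First, the N(N-1)/2 pairs share
genomes and are therefore not independent observations; the p-values are
used as a comparable ranking score across estimators, not as calibrated
significance tests. Second, the p-value's sidedness is configurable
(`two_sided` default, `negative` available) and recorded in the result
object, since the expected direction is known in advance.

## The estimators

**Exact Jaccard.** Genomes are decomposed into their distinct k-mers
(multiplicity ignored); `exact_jaccard()` returns
\(J = |K_a \cap K_b| / |K_a \cup K_b|\). K-mers are canonical by default
(a k-mer and its reverse complement are collapsed, as in Mash), windows
containing any non-ACGT character are skipped, and k-mers never span record
boundaries in a multi-record assembly. K-mers are hashed with a seedable
splitmix64 over the 2-bit packing, truncated to the top 53 bits so every
hash is exactly representable as an R double; at 5M k-mers per genome the
truncation's collision mass (~1e-3 expected collisions per pair) is
negligible relative to sketch noise.

**MinHash sketch and Mash distance.** `build_sketch()` keeps the s smallest
hash values. `sketch_jaccard()` defaults to the merged-sketch estimator the
Mash tool actually computes — the fraction of the s smallest values of the
*union* of the two sketches that occur in both — because fidelity to the
benchmarked software matters more than the textbook intersection/union form,
which remains available via `literal = TRUE`. `mash_index()` applies
\(1 + \frac{1}{k}\ln\frac{2J}{1+J}\); at \(J = 0\) the logarithm diverges,
so the result saturates at distance 1 / index 0 with a `saturated` flag
(the Mash convention).

**ANIb.** The query is cut into consecutive 1020-bp fragments (a trailing
fragment is kept only if at least 100 bp — the classical protocol does not
specify this; the choice is documented here and only perturbs AF at the
fourth decimal for Mbp genomes). Each fragment's best seeded, banded local
alignment against either strand of the reference is retained iff identity
> 30% and fragment coverage > 70%; ANI is the *unweighted* mean identity of
retained fragments (matching the "average identity of all matches"
definition) and AF is retained-fragment bases over query length. ANIb is
deliberately asymmetric in (query, reference).

**OrthoANI.** Both genomes are fragmented; each fragment's best hit against
the whole other genome nominates a partner fragment (the one containing the
hit midpoint), and only *reciprocal* best pairs contribute, each with the
mean of its two directional identities. A best hit must cover at least 35%
of its fragment to be eligible — without this rule, short perfect local
matches between non-homologous fragments dominate distant pairs and push
their mean identity toward 100%, inverting the expected ranking.

**ANIm.** A NUCmer-like pipeline: maximal exact matches (MEMs) of length
\(\ge \ell\) on both strands are found with a suffix-array/LCP structure
(verified against a brute-force longest-common-extension oracle in the test
suite); in `mum` mode only matches whose substring occurs exactly once in
each sequence are kept. Anchors are chained into collinear clusters
(coordinate gaps \(\le\) 90 on both axes, NUCmer's documented cluster gap;
clusters below 65 total anchor bases are dropped, NUCmer's cluster-length
default), each cluster is extended into one alignment by closing
inter-anchor gaps with banded global alignment (band = gap-length difference
+ 20), and optionally a 1-to-1 filter retains a maximum-weight subset of
hits that are non-overlapping on both axes (delta-filter -1 semantics; exact
branch-and-bound up to 25 hits, greedy beyond). ANI is the
alignment-length-weighted identity over retained hits (as in PyANI's ANIm);
AF counts aligned bases on both genomes over the summed lengths. With no
retained hits ANI and AF are 0 and flagged — reproducing ANIm's
characteristic zero-ANI failure on moderately distant genomes, which is
also why lowering \(\ell\) from 20 to 14 recovers non-zero values on more
pairs.

**Digital-DDH formulas.** From a pool of local alignments (both comparison
directions), `ddh_distances()` returns d1 = 1 - alignment length / summed
genome length (one minus AF), d2 = 1 - identities / alignment length, and
d3 = 1 - identities / summed genome length; d2 is undefined (flagged NA)
without alignments. The regression-based conversion of these distances to
DDH percentages is out of scope.

**Scoring.** All alignments use an affine-gap scheme, default +1/-2/-5/-2
(match/mismatch/open/extend), blastn-like and configurable. A gap of length
g costs `gap_open + g * gap_extend`.

## The genome-evolution simulator

`simulate_dataset()` provides genomes with a *known* truth: a species tree,
an event log, and a per-gene orthology table.

* **Tree.** A birth-death tree conditioned on n surviving leaves
  (birth 0.01, death 0.001 per lineage by default; sampled via
  `ape::rphylo`), rescaled so every root-to-leaf path equals the
  `root_to_leaf_len` parameter. The topology depends only on the master
  seed, so scenarios that vary event rates share one topology, and
  replicates share the tree while differing in the mutation RNG stream.
* **Root genome.** 100 genes of 50 kb by default (5 Mbp), i.i.d. uniform
  ACGT. Genes are contiguous blocks with zero-length intergenic space —
  gene boundaries are bookkeeping for duplication/transfer, not sequence.
* **Substitutions.** Jukes-Cantor at the nucleotide level. Branch lengths
  are in PAM-like units — one unit is one expected substitution per 100
  sites — so over a branch of length t each site differs from its ancestor
  with probability \(\frac34(1 - e^{-\frac43 t/100})\). This is a stand-in
  for an amino-acid-level substitution process; absolute ANI-vs-branch
  calibration therefore differs from protein-model simulators, but every
  statistic in the benchmark is rank-based and unaffected by monotone
  recalibration of the divergence axis.
* **Indels.** Poisson per site at rate `indel_rate` (1e-4) per branch-length
  unit; lengths Zipf with exponent 1.8 truncated at 50 bp (values chosen as
  typical for this simulator family), insertion/deletion equiprobable,
  uniform positions, deletions truncated at gene boundaries and never
  deleting a gene entirely.
* **Duplication and LGT.** Rates are per gene per branch-length unit, so
  the studied magnitudes 0.0005-0.002 yield a few to tens of events per
  lineage over a root-to-leaf length of 100 — the regime in which
  duplication and transfer visibly perturb anchoring and AF. (Interpreting
  the same numbers per 100-unit branch instead would give ~0.2 events per
  lineage at the maximum rate, a regime in which the duplication/LGT
  scenarios would be indistinguishable from the null; the per-unit
  convention is this package's documented choice.) Duplications copy a
  uniformly chosen gene to a uniform intergenic slot. LGT runs on a
  discrete time grid of step `root_to_leaf_len`/100: lineages alive in a
  step exchange Poisson-many genes, donor and recipient drawn uniformly
  (donor ≠ recipient; only extant lineages exist in the conditioned tree),
  and every event is logged with time, family and recipient position.
* **Ground truth.** The ortholog table records per-genome family copy
  numbers; `one_to_one_families()` yields the 1:1 families of a pair, and
  `gene_sequences()` extracts gene subsets, enabling orthologous-subset
  Jaccard experiments without any orthology inference.

What the simulator does *not* emulate: rate heterogeneity across sites or
lineages, codon/amino-acid structure, GC-content drift, rearrangement and
inversion, gene loss, repeat families, and assembly artifacts. Passing
benchmarks on this generator demonstrates algorithmic correctness and the
qualitative mechanisms (anchoring failure at distance, duplication's effect
on unique-match anchoring, sketching noise), not performance on real
assemblies.

## Statistical machinery

Ranks use average-rank tie handling; rho is the Pearson correlation of
ranks. For n > 8 the p-value comes from the t approximation
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) with the tail computed by `pt(...,
log.p = TRUE)`, i.e. entirely in log space, so values like log10 p = -150
are exact rather than underflowed zeros; |rho| = 1 is reported as the
documented cap log10 p = -320 with a flag. For n ≤ 8 the exact permutation
distribution over all n! reorderings is used instead. Constant inputs yield
a flagged NA rather than an error, so sweeps over degenerate columns do not
abort.

Zero or missing estimates (ANIm's zero-ANI pairs, unreported FastANI pairs)
are kept: zeros carry rank information and are included by default, while
truly missing entries are flagged in the pair table (`complete`) and dropped
pairwise by the correlation with the count reported in `n`.

The bi-k merged ranking (`merged_rank_distance()`) ranks each column,
averages the two rank vectors, and re-ranks the averages; it is the
mechanism for combining the complementary information of a short and a long
k-mer length when the k-sweep shows two local minima.

## Numerical and design choices

* 0-based half-open coordinates everywhere in memory; conversion only at
  I/O boundaries.
* Minus-strand anchors are reported in the searched-strand frame (keeping
  them collinear for chaining) and mapped back to forward coordinates when
  an alignment hit is emitted. In `mum` mode uniqueness is assessed within
  the query and the searched strand of the reference.
* The fragment aligner seeds with shared 11-mers, votes diagonal buckets,
  and refines the top buckets with banded local alignment (band 50 by
  default); band storage is compressed to the diagonal window, and a
  banded score can never exceed the full-DP score (property-tested).
* Chain extraction is greedy: repeatedly take the maximum-weight collinear
  chain (weighted LIS; ties broken by anchor order) and remove its anchors.
* `filter_one_to_one()` optimizes the summed matched bases exactly (branch
  and bound) up to 25 hits — comfortably covering the exhaustive-oracle
  regime — and falls back to greedy weight-ordered selection beyond.
* Sketch serialization is a one-hash-per-line TSV with a header carrying
  k, s, seed and the canonical flag, so sketches are portable and
  reproducible across sessions.

## Problem sizes used in tests and the acceptance script

The packaged checks run the full pipeline at desk scale: 15-leaf trees with
10 genes x 2.5 kb genomes (25 kb) for the divergence, ranking and
minimum-match-length experiments; 100 genes x 0.5 kb (50 kb) with
duplication rate 0.002 for the MEM-vs-MUM alignment-fraction comparison;
30 kb genomes for sketch-convergence checks; and the unmodified study
configuration (100 x 50 kb) for the root-genome contract. These sizes are
the package's choice of a benchmark that exercises every code path with
hundreds of anchors and thousands of fragments per run while keeping the
whole suite reproducible in minutes; the statistics they produce are
qualitative replications (directions, orderings, monotonicities), not
numerical reproductions of results obtained under protein-level simulation
on Mbp genomes.

## Known limitations

* The Jukes-Cantor stand-in makes absolute ANI values at a given branch
  length systematically different from protein-model simulators; only ranks
  are comparable.
* ANIb/OrthoANI here use a seeded banded aligner, not BLAST; scores are not
  bit-exact with BLAST-based implementations, and e-values are not
  computed.
* The 1-to-1 filter's greedy fallback (> 25 hits) is not guaranteed
  optimal, mirroring the sequential LIS heuristic of the emulated tool.
* FastANI, Dashing and friends are supported through output adapters
  (`parse_external_tool_output()`), not reimplemented.
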