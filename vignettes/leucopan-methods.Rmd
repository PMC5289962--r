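---
title: "Methods: pan-genome lineage typing and marker-based quantification"
author: "leucopan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome lineage typing and marker-based quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`leucopan` implements the computational chain used to characterize
*Leuconostoc* populations in mixed mesophilic (DL-type) dairy starter
cultures: ortholog clustering of annotated gene sets into a pan/core
genome, lineage differentiation on the presence/absence pan-matrix with an
automatic cluster-count cut-off, screening of core genes for an amplicon
marker with conserved primer flanks, and relative quantification of
species from paired-end amplicon reads. A synthetic-data module generates
genome populations with planted structure and mock-community reads so that
every stage can be validated against a known truth without external data.

This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and the design decisions taken where the
methods left genuine freedom. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Synthetic genome populations

`lineage_model()` describes a population with three family classes:

* **core families** (default 400) present in every genome;
* a **shared accessory pool** (default 200) whose families are present in
  each genome independently with probability 1/2, regardless of lineage —
  this is the unstructured noise floor of the pan-matrix;
* **lineage accessory blocks** (default 50 per lineage) private to each of
  the `n_lineages` (default 6) lineages of `genomes_per_lineage`
  (default 4) genomes — these carry the planted signal.

Gain/loss noise flips accessory presence cells with per-cell Bernoulli
rates (`gain_rate`, `loss_rate`, default 0.05 each). Core families are
exempt from loss so the strict core survives by construction; without this
exemption a "core" would not exist to recover, and the generator's own
contract (every genome contains all core families) could not hold.

Sequence evolution is a star phylogeny per family with i.i.d.
substitutions and no indels (an indel-free model is the simplest one that
exercises ortholog clustering and alignment; alignment columns then map
1:1 to sequence positions, which the tests exploit). Divergences are given
in expected substitutions/site and converted to per-site difference
probabilities with the Jukes–Cantor saturation map
`p = 3/4 (1 - exp(-4d/3))`. Family ancestors diverge from one population
root at `between_family_divergence` (default 1.5, i.e. near-saturated
`p ≈ 0.65`); gene copies diverge from their family ancestor at
`within_family_divergence` (default 0.02, matching the ~98–99% nucleotide
identity typical of conspecific dairy isolates). Two tips at per-site
difference probability `p` from their ancestor then match at a site with
probability `(1-p)^2 + p^2/3`, the closed form the tests check empirically.
Genes are built from non-stop codons; substitutions creating an in-frame
stop are repaired deterministically (second codon base set to `C`) so
translations remain valid; the tests tolerate the tiny identity bias this
introduces.

Gene lengths default to 240–450 bp (80–150 codons). This is the package's
desk-scale problem size: it preserves everything the clustering stages are
sensitive to (within/between-family identity contrast, length variation,
coverage gating) while keeping the default 24-genome population at roughly
13,000 genes.

## Ortholog clustering

`all_vs_all_similarity()` re-implements the all-against-all protein
comparison as banded Smith–Waterman (BLOSUM62, gap open 11 / extend 1).
An edge is emitted iff alignment identity ≥ `min_identity` (0.30) and
coverage — the aligned span of the *shorter* sequence divided by its
length — ≥ `min_coverage` (0.75); these mirror common ortholog-pipeline
defaults — the field's BLASTP-based pipelines rarely publish these
cut-offs, so they must be declared here.
The edge weight is the raw alignment score normalized by the
self-alignment score of the shorter sequence, so identical sequences score
exactly 1.

Two speed heuristics are declared, configurable parameters rather than
silent shortcuts:

* a sampled amino-acid k-mer prefilter (`kmer_len = 5`,
  `kmer_stride = 7`, `min_shared_kmers = 1`): only gene pairs sharing a
  sampled k-mer are aligned. At the default within-family divergence the
  probability that a true pair shares no sampled k-mer is negligible; the
  filter's sensitivity floor (~30–40% identity for unrelated-length
  genes) sits at the same twilight zone as the identity gate itself.
* a diagonal band of half-width `|len_a - len_b| + band_extra`
  (`band_extra = 24`) in the DP matrix. Under the indel-free generator the
  optimal path never leaves the band; for real data with large indels the
  band (or the prefilter) can be widened or disabled.

Sub-threshold alignments (score > 0 but failing a gate) are retained as a
`hits` attribute. They play one role: singleton curation (below).

`mcl_cluster()` is a faithful dense implementation of the Markov Cluster
Algorithm at inflation 1.5: self-loops equal to each node's maximum
incident edge weight, column normalization, expansion (matrix square)
alternating with inflation (entrywise power, renormalize), convergence
when the largest entry change falls below `1e-6` (error on
non-convergence at `max_mcl_iters`). The converged flow matrix is read by
assigning every node to its highest-flow attractor (ties to the
lexicographically first), merging attractors that retain flow on one
another. Clustering runs per connected component of the similarity graph,
which cannot change the result and keeps the matrices small. The test
suite checks the partition against a second, independently written MCL
implementation on random graphs.

**Singleton curation.** The curated quantity is "significantly divergent
singletons", operationalized as: a singleton group whose gene's best-hit
identity is below `singleton_curation_identity` (0.5) *and* whose length
deviates from that best hit by more than `singleton_length_deviation`
(0.5). Two observations shaped the mechanics:

* MCL assigns every connected node to a cluster, so a gene with any gated
  edge never becomes a singleton — divergent fragments reach the curator
  only by failing the edge gates, i.e. as isolated nodes;
* an isolated node with *no* similarity information at all is a novel
  gene, which must be kept.

The curator therefore takes a singleton's best identity from the gated
edges *plus* the sub-threshold hits covering at least
`singleton_hit_coverage` (0.3) of the shorter sequence. The coverage floor
excludes meaningless micro-islands (a five-residue exact match has
identity 1.0 but says nothing about the gene), while still seeing the
twilight-zone alignments that mark a diverged fragment of a real family.

`build_pan_matrix()` collapses paralogs to presence/absence (per-genome
copy numbers are observable in the membership table, but the downstream
lineage analysis operates on presence only).

## Pan/core estimation

`accumulation_curves()` adds genomes one at a time in random order,
tracking the union (pan) and intersection (core) of OG sets; means and
standard deviations are taken over `n_orders = 1000` uniform permutations,
with exhaustive enumeration replacing sampling whenever `N! ≤ n_orders`.
Per-order monotonicity (pan non-decreasing, core non-increasing) is
asserted in the tests, not just on the means.

`fit_curves()` fits the standard pan-genome tool family's forms by
nonlinear least squares (`minpack.lm`): a Heaps/Tettelin-style power law
`y = A n^B + C` for the pan curve and an exponential decay
`y = A e^{Bn} + C` for the core. The pan-genome is classified *open* when
the fitted exponent exceeds zero by more than three standard errors. A
perfectly flat curve short-circuits to `B = 0`, closed, rather than
failing on a singular gradient. The strict core (families in 100% of
genomes) is the reported core size; a `soft_core_fraction` flag exists for
softer definitions.

## Lineage typing

Distances are Manhattan distances between pan-matrix rows (on binary rows,
the count of discordant OGs). Agglomerative clustering defaults to
**complete linkage**: the description "complete-linkage UPGMA" is
internally contradictory (UPGMA *is* average linkage), so the more
specific term wins and average linkage stays available by flag.

The cluster count is selected with the **L-method** knee of the
evaluation graph: x = number of clusters (2..`k_max`, default
`min(N-1, 20)`), y = the merge height at which x clusters collapse to
x − 1. For each candidate knee c, least-squares lines are fitted to the
points with x ≤ c and x > c and c minimizing the point-count-weighted
total RMSE is chosen; the candidate range is then iteratively shrunk
toward twice the current knee until stable. With this graph convention the
last point of the steep segment sits exactly at the planted cluster count.
x = 1 is excluded (a one-cluster solution has no merge cost), so the
smallest detectable k is 3; a flat height profile returns k = 1 with a
warning. The automatic k and the full curve are both reported, so a user
who judges a different lineage count more robust can override the cut with
`assign_lineages(tree, k)` at any k.

Lineage labels are stable: lineages are numbered by the lexicographically
smallest genome they contain, so permuting the input permutes labels but
never the partition.

Trait tables render per-lineage presence fractions the way published
genotype tables do: `+` when every member carries at least one OG of the
trait set, `-` when none does, otherwise `+(NN%)` with NN the percentage
*truncated* to an integer (2 of 3 members renders `+(66%)`, matching the
published convention).

## Marker screening

`align_cluster()` is a center-star multiple aligner (match +1, mismatch
−1, linear gap −2): the center is the sequence with the highest summed
pairwise global-alignment score, the others are merged against it under
"once a gap, always a gap" with insertion blocks left-justified. A
numerical subtlety: with these integer costs a gapped and an ungapped
alignment can tie exactly, and the pairwise aligner may return the gapped
one, padding the MSA with a spurious column; an infinitesimal surcharge
(`1e-6`) on the gap cost resolves such ties toward the ungapped optimum
while leaving genuine indels untouched.

`conservation_profile()` scores each column by modal-symbol fraction (not
entropy — the flank requirement is "every species matches the primer",
which is a consensus statement), plus a per-column gap fraction.

`scan_candidate_windows()` slides a `window_len` (500 bp) variable window
and requires (a) the `flank_len` (25 bp) columns abutting *each end* of
the window to be gap-free at consensus ≥ `flank_min_consensus` (1.0 —
primers must match every species), and (b) the minimum pairwise difference
count between members of different species inside the window to reach
`min_interspecies_diffs` (5). Qualifying windows are ranked by that
discrimination count, then window variability, then position; overlapping
placements are coalesced to the best-ranked one, so each reported
candidate is one distinct amplicon region. Primers are the 5' flank
consensus and the reverse complement of the 3' flank consensus; window
coordinates are reported in both alignment and ungapped
representative-sequence coordinates.

`offtarget_filter()` removes a candidate when, for any off-target
sequence, both primers match (either strand, IUPAC-aware, within
`max_primer_mismatches` = 2) or the window consensus aligns at identity ≥
`max_offtarget_identity` (0.85). This mirrors rejecting 16S and *rpoB*
style loci that cross-react with lactococci. The exact thresholds are
declared knobs: the original exclusion criteria were qualitative.

`locate_primers()` finds the forward primer and the reverse primer's
reverse complement downstream on a template (≤ `max_mismatches` each,
IUPAC-aware) and returns the outermost primer-inclusive interval, leftmost
on overlapping ties; multiple *non-overlapping* amplicons raise an error
to force an explicit choice. `eno_primers()` ships the published
Eno-F/Eno-R pair.

## Amplicon quantification

`merge_pairs()` reverse-complements R2 and scores every suffix–prefix
overlap ≥ `min_overlap` (20 bp) with +1/−1; the best-scoring overlap
(ties to the longer) is accepted iff its mismatch fraction is ≤
`max_overlap_mismatch_frac` (0.1). Consensus bases keep the agreeing base
at quality `max(q1, q2)`; conflicts take the higher-quality base at
quality `|q1 − q2|`. This replaces a statistical overlap test with a
transparent score gate whose behavior is directly testable.

`quality_filter()` keeps reads with expected errors `Σ 10^(−q/10)` ≤
`max_expected_errors` (1.0), the standard amplicon criterion; a mean-Q ≥
20 alternative is available by flag for fidelity to shotgun-style
filtering. Note the conflict-quality rule above makes expected errors
spike exactly for reads with overlap disagreements, so the filter
preferentially discards reads carrying errors in the double-covered
region.

`dereplicate()` groups reads at 100% identity (exact, case-normalized,
full length), sorted by abundance then lexicographically. `denoise()` is
a greedy abundance-ordered pass: a sequence is absorbed into the most
abundant existing centroid within `denoise_max_diffs` (1) substitutions
whose current abundance is at least `denoise_abundance_skew` (8) times
its own, otherwise it becomes a centroid.

**Singleton discard is off by default.** The uparse-style
`discard_singletons = TRUE` guards de-novo OTU inference against spurious
OTUs. Here abundance is aggregated by *reference classification*: every
centroid is globally aligned to the marker allele database and assigned
its top-hit species at identity ≥ `min_classify_identity` (0.97), exact
inter-species ties giving `ambiguous`. In this design an error-bearing
singleton still classifies to its source species, so discarding singletons
only throws away signal — and does so asymmetrically: at realistic error
rates a 550 bp amplicon read almost always carries ≥ 2 substitutions, so
with discard on, only the few exact or 1-error reads survive and species
whose exact-sequence abundance never clears the 8× skew gate vanish
entirely. Implementation proved the discard default wrong for this
pipeline (composition errors of tens of percentage points at the default
mock-community conditions); with singletons retained the same conditions
are recovered to well under one percentage point. The flag remains
available for de-novo-style use.

Classification uses an exact Hamming fast path when centroid and
reference have equal length (`(L−d)/L` equals global-alignment identity
whenever the optimal alignment is gap-free, which holds in the
near-identity regime that matters at the 0.97 gate) and falls back to
affine-gap global alignment for length mismatches. A label-merge map can
collapse species a marker cannot separate (e.g. *Ln. mesenteroides* /
*Ln. dextranicum*) before tie evaluation.

`compose()` reports, per replicate, each species' share of total centroid
abundance, with ambiguous and unclassified pooled into an `unclassified`
fraction so per-replicate fractions sum to one; means and standard
deviations are taken over replicates, and a replicate with zero classified
reads is excluded from the mean with a warning. Read counts are tracked at
every stage (`quantify_amplicons()$stage_counts`) so conservation —
input = merged + unmerged; merged = pass + fail QC; centroid reads ≤
unique reads — can be audited.

## Mock communities

`mock_community()` defaults mirror a triplicate MiSeq amplicon
experiment over the default marker locus: three species at
0.60/0.25/0.15, 10,000 read pairs per replicate, three replicates, 2 ×
300 bp reads over the 550 bp amplicon (25 bp flanks + 500 bp variable
region), 1% i.i.d. per-base substitution errors, Phred qualities from a
clipped normal (mean 35, sd 3, bounds 2–41). Errors are independent of
the quality values — a deliberate simplification. Real instrument errors
are strongly quality-correlated, which makes expected-error filtering far
more informative on real data than on these simulations; conversely,
passing the synthetic recovery tests does not demonstrate robustness to
quality-correlated error structure, chimeras or PCR bias, all of which
are out of scope.

## Problem sizes and determinism

The default synthetic study — 24 genomes in 6 lineages, 400 core + 200
shared + 50/lineage accessory families, 240–450 bp genes, and 3 × 10,000
read pairs — was chosen so the full chain runs in well under a minute and
a ten-seed recovery sweep in a few minutes on one CPU, while keeping every
contrast (within/between family identity, lineage separation versus
accessory noise, error load per amplicon) at realistic ratios. All
generators are deterministic under their seed, byte-for-byte, and the
amplicon pipeline itself contains no randomness.

## Known limitations

* The similarity engine's k-mer prefilter and band are heuristics; their
  misses concentrate in the twilight zone (< 35% identity) and at large
  indels, where the edge gates would mostly reject pairs anyway.
* MCL granularity is controlled only by inflation (1.5); weakly attached
  genuine paralogs join their family cluster rather than splitting.
* The L-method cannot return k = 2 (its leftmost candidate knee is 3);
  populations with two lineages need a manual cut.
* Center-star alignment is optimal for the indel-free generator but only
  an approximation for indel-rich families.
* Openness classification inherits the usual caveat that accumulation
  curves are not independent samples; the 3σ rule on the fitted exponent
  is a heuristic, not a test with calibrated error rates.
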