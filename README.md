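# leucopan

Pan-genome lineage typing and marker-gene quantification of dairy
*Leuconostoc*.

Undefined mesophilic (DL-type) starter cultures are dominated by
*Lactococcus lactis* with a 1–10% *Leuconostoc* fraction whose species and
subspecies composition shapes the aroma and texture of the final product —
and which classical plating badly misrepresents, since some dairy
*Ln. mesenteroides* subsp. *cremoris* types barely grow on standard media.
`leucopan` implements, as a tested R package, the genomics workflow for
characterizing such populations:

1. **Ortholog clustering** — all-against-all protein comparison
   (banded Smith–Waterman, BLOSUM62), Markov clustering (MCL, inflation
   1.5) into orthologous groups (OGs), curation of divergent singleton
   fragments, and the binary genome × OG **pan-matrix**.
2. **Pan/core estimation** — accumulation curves over random genome
   orderings with Heaps-style fits: pan `y = A·n^B + C` (open iff B > 0 by
   more than 3 SE), core `y = A·e^{Bn} + C`; strict-core reporting and
   per-lineage genome summaries.
3. **Lineage typing** — Manhattan distances on the pan-matrix,
   complete-linkage clustering, automatic cluster-count selection by the
   L-method knee of the merge-height curve, stable lineage labels, and
   genotype-style trait tables rendered as `+`, `-`, `+(NN%)`.
4. **Marker screening** — center-star alignment of core genes,
   conservation profiling, discovery of ~500 bp variable windows with
   perfectly conserved primer-length flanks, species-discrimination
   scoring, off-target (cross-reactivity) filtering, and in-silico primer
   location; the published enolase primers ship as `eno_primers()`.
5. **Amplicon quantification** — paired-end merging with quality-aware
   consensus, expected-error filtering, 100%-identity dereplication,
   abundance-skew denoising, reference classification, and replicate-
   averaged composition tables with full read-count accounting.
6. **Synthetic data** — genome populations with planted lineage structure
   (core / shared-accessory / lineage-accessory families, gain/loss noise,
   Jukes–Cantor star-phylogeny divergence) and mock-community paired reads
   with a substitution error model, plus the ground truth to score
   recovery. Everything is deterministic under a seed.

## Worked example

```r
library(leucopan)

## a 24-genome population with 6 planted lineages, default noise
pop  <- generate_pangenome_population(lineage_model(seed = 1))
res  <- cluster_proteomes(pop$proteins)
report_pan_core(res$pan)
#> Pan-genome: 900 OGs; core genome: 400 OGs
#> Per-genome OG counts: 544-570 (range)

tree <- agglomerative_cluster(manhattan_distances(res$pan))
k    <- knee_select_k(tree)
assign_lineages(tree, k)
#> Lineage assignment: k = 6 (cut height 177 )
#> L1 L2 L3 L4 L5 L6
#>  4  4  4  4  4  4
```

The clustering recovered all 900 planted gene families, the strict core
(400 OGs) and the six planted lineages exactly (adjusted Rand index 1
against the generator's truth labels).

```r
## marker screen on a planted enolase-like locus
alleles <- generate_marker_alleles(marker_model(seed = 2))
aln     <- align_cluster(alleles)
scan_candidate_windows(conservation_profile(aln), aln,
                       allele_species(alleles), og_id = "eno")
#>   og_id win_start win_end discrimination                primer_fwd
#> 1   eno        25     525             11 AGCCTTAAATAACGAGCTTCGGGTG
```

One candidate: the 500 bp variable window at alignment position 25
(0-based, half-open), i.e. exactly between the two 25 bp conserved
flanks, with a minimum of 11 differences between any two species.

```r
## mock community 60/25/15, 3 x 10,000 read pairs, 1% per-base error
reads <- simulate_amplicon_reads(mock_community(seed = 3), alleles)
quantify_amplicons(reads, alleles)$composition
#> Species composition over 3 replicate(s):
#>                 species  mean   sd
#>             Ln_cremoris 60.84 0.14
#>        Ln_mesenteroides 14.94 0.30
#>  Ln_pseudomesenteroides 24.22 0.23
#>            unclassified  0.00 0.00
#> (mean/sd in percent)
```

Every species is recovered within one percentage point of its true
proportion.

A command-line wrapper over the same functions lives in
`inst/scripts/leucopan` (subcommands `simulate`, `cluster`, `pancore`,
`lineages`, `marker-screen`, `quantify`), writing TSV/Newick/FASTA
outputs per stage.

## Package layout

* `R/io-*.R` — FASTA/FASTQ (Phred+33) readers/writers, contig
  length/coverage curation, Newick export, INI-style configuration.
* `R/simulate-*.R` — population, marker-allele and read generators.
* `R/ortholog-*.R` — similarity engine, MCL, curation, pan-matrix.
* `R/pangenome-*.R` — accumulation curves, fits, reports.
* `R/lineage-typing.R` — distances, clustering, L-method, lineage
  assignment, trait tables.
* `R/marker-*.R` — center-star MSA, conservation, window scan, off-target
  filter, primer location.
* `R/amplicon-*.R` — merge, filter, dereplicate, denoise, classify,
  compose.
* `src/kernels.cpp` — Smith–Waterman statistics, Hamming distances,
  read-pair merging.
* `vignettes/leucopan-methods.Rmd` — models, parameter rationale, design
  decisions, limitations.
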