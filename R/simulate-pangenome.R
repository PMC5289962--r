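#' Lineage model for synthetic genome populations
#'
#' Describes a genome population with planted structure: a strict set of core
#' gene families shared by every genome, a pool of shared accessory families
#' scattered across genomes irrespective of lineage, and per-lineage
#' accessory blocks that make lineages separable on the presence/absence
#' pan-matrix. Per-family sequence divergence follows a star phylogeny with
#' i.i.d. substitutions; expected substitutions/site are converted to
#' per-site difference probabilities with the Jukes-Cantor saturation map
#' `p = 3/4 (1 - exp(-4 d / 3))`.
#'
#' @param n_lineages number of planted lineages.
#' @param genomes_per_lineage genomes per lineage (scalar or vector).
#' @param core_families number of families present in every genome.
#' @param shared_accessory_pool families present in random genome subsets
#'   (presence probability 1/2 each), independent of lineage.
#' @param lineage_accessory_per_lineage families private to each lineage.
#' @param gain_rate,loss_rate per-genome, per-family Bernoulli rates of
#'   accessory gene gain (where the design says absent) and loss (where it
#'   says present). Core families are exempt from loss so the strict core is
#'   preserved by construction.
#' @param within_family_divergence expected substitutions/site between a
#'   family's ancestral sequence and each gene copy (0-0.3).
#' @param between_family_divergence expected substitutions/site between the
#'   population root and each family ancestor; must exceed the within-family
#'   divergence.
#' @param gene_length_range bp range genes are drawn from (rounded to codons).
#' @param seed RNG seed; identical seeds give byte-identical output.
#' @return a validated `lineage_model` list.
#' @export
lineage_model <- function(n_lineages = 6, genomes_per_lineage = 4,
                          core_families = 400, shared_accessory_pool = 200,
                          lineage_accessory_per_lineage = 50,
                          gain_rate = 0.05, loss_rate = 0.05,
                          within_family_divergence = 0.02,
                          between_family_divergence = 1.5,
                          gene_length_range = c(240, 450), seed = 1) {
  m <- list(n_lineages = n_lineages,
            genomes_per_lineage = rep(genomes_per_lineage,
                                      length.out = n_lineages),
            core_families = core_families,
            shared_accessory_pool = shared_accessory_pool,
            lineage_accessory_per_lineage = lineage_accessory_per_lineage,
            gain_rate = gain_rate, loss_rate = loss_rate,
            within_family_divergence = within_family_divergence,
            between_family_divergence = between_family_divergence,
            gene_length_range = sort(gene_length_range), seed = seed)
  assert_that(n_lineages >= 1 && all(m$genomes_per_lineage >= 1),
              "need at least one genome per lineage")
  assert_that(core_families >= 1, "need at least one core family")
  assert_that(shared_accessory_pool >= 0 &&
                lineage_accessory_per_lineage >= 0,
              "accessory pool sizes must be >= 0")
  assert_that(gain_rate >= 0 && gain_rate <= 1 &&
                loss_rate >= 0 && loss_rate <= 1,
              "gain/loss rates must lie in [0, 1]")
  assert_that(within_family_divergence >= 0 &&
                within_family_divergence <= 0.3,
              "within_family_divergence must lie in [0, 0.3]")
  assert_that(between_family_divergence > within_family_divergence,
              "between_family_divergence must exceed within_family_divergence")
  assert_that(m$gene_length_range[1] >= 30,
              "genes must be at least 30 bp")
  structure(m, class = "lineage_model")
}

# Jukes-Cantor: expected substitutions/site -> per-site difference probability.
jc_p_diff <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Expected pairwise identity of two tips each at per-site difference
# probability p from their common ancestor: both unchanged, or both changed
# to the same one of the three alternatives.
jc_pair_identity <- function(p) (1 - p)^2 + p^2 / 3

non_stop_codons <- function() {
  if (is.null(pkg_cache$NON_STOP_CODONS))
    pkg_cache$NON_STOP_CODONS <- setdiff(
      apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
            collapse = ""),
      STOP_CODONS)
  pkg_cache$NON_STOP_CODONS
}

random_orf <- function(n_codons) {
  unlist(strsplit(sample(non_stop_codons(), n_codons, replace = TRUE), ""))
}

# i.i.d. substitutions on a base vector at per-site probability p; codons
# mutated into stops are repaired deterministically (second base -> C) so
# translations stay open-reading-frame.
mutate_orf <- function(bases, p) {
  L <- length(bases)
  idx <- which(runif(L) < p)
  if (length(idx) > 0) {
    cur <- bases[idx]
    pick <- function(b) DNA_BASES[DNA_BASES != b][sample.int(3L, 1L)]
    bases[idx] <- vapply(cur, pick, character(1), USE.NAMES = FALSE)
    starts <- seq(1L, L, by = 3L)
    cods <- paste0(bases[starts], bases[starts + 1L], bases[starts + 2L])
    bad <- which(cods %in% STOP_CODONS)
    if (length(bad) > 0) bases[starts[bad] + 1L] <- "C"
  }
  bases
}

#' Generate a genome population with planted lineage structure
#'
#' Produces per-genome gene sets (nucleotide ORFs and their translations)
#' and the ground truth needed to score downstream recovery: the gene-to-
#' family map, the genome-to-lineage map, and the realized presence/absence
#' matrix (the noiseless block design plus any gain/loss noise).
#'
#' @param model a [lineage_model()].
#' @param dir optional directory; when given, per-genome FASTA files
#'   (`genes/<genome>.fna`, `proteins/<genome>.faa`) and truth TSVs are
#'   written there.
#' @return list with `genes` (named list of `DNAStringSet`), `proteins`
#'   (named list of `AAStringSet`), and `truth` (list: `family_of_gene`,
#'   `lineage_of_genome`, `planted_presence`).
#' @export
generate_pangenome_population <- function(model, dir = NULL) {
  assert_that(inherits(model, "lineage_model"),
              "model must come from lineage_model()")
  set.seed(model$seed)
  n_gen <- sum(model$genomes_per_lineage)
  genomes <- sprintf("G%02d", seq_len(n_gen))
  lineage_of_genome <- rep(sprintf("L%d", seq_len(model$n_lineages)),
                           times = model$genomes_per_lineage)
  names(lineage_of_genome) <- genomes

  n_core <- model$core_families
  n_shared <- model$shared_accessory_pool
  n_lacc <- model$lineage_accessory_per_lineage * model$n_lineages
  n_fam <- n_core + n_shared + n_lacc
  fams <- sprintf("F%04d", seq_len(n_fam))
  fam_type <- c(rep("core", n_core), rep("shared", n_shared),
                rep("lineage", n_lacc))
  fam_lineage <- rep(NA_character_, n_fam)
  if (n_lacc > 0)
    fam_lineage[fam_type == "lineage"] <-
      rep(sprintf("L%d", seq_len(model$n_lineages)),
          each = model$lineage_accessory_per_lineage)

  # block design, then gain/loss noise (core exempt from loss)
  pres <- matrix(0L, n_gen, n_fam, dimnames = list(genomes, fams))
  pres[, fam_type == "core"] <- 1L
  if (n_shared > 0)
    pres[, fam_type == "shared"] <-
      matrix(rbinom(n_gen * n_shared, 1L, 0.5), n_gen, n_shared)
  for (f in which(fam_type == "lineage"))
    pres[lineage_of_genome == fam_lineage[f], f] <- 1L
  noise_ok <- fam_type != "core"
  if (model$loss_rate > 0 || model$gain_rate > 0) {
    flip <- matrix(runif(n_gen * n_fam), n_gen, n_fam)
    lose <- pres == 1L & rep(noise_ok, each = n_gen) & flip < model$loss_rate
    gain <- pres == 0L & flip < model$gain_rate
    pres[lose] <- 0L
    pres[gain] <- 1L
  }
  keep_fam <- colSums(pres) > 0
  pres <- pres[, keep_fam, drop = FALSE]
  fams <- fams[keep_fam]

  # ancestral sequences: family ancestors diverge from one population root
  len_rng <- model$gene_length_range
  codon_choices <- seq(ceiling(len_rng[1] / 3), floor(len_rng[2] / 3))
  n_codons <- codon_choices[sample.int(length(codon_choices), length(fams),
                                       replace = TRUE)]
  root <- random_orf(max(n_codons))
  p_between <- jc_p_diff(model$between_family_divergence)
  p_within <- jc_p_diff(model$within_family_divergence)
  ancestors <- lapply(n_codons, function(nc)
    mutate_orf(root[seq_len(3L * nc)], p_between))
  names(ancestors) <- fams

  genes <- vector("list", n_gen); names(genes) <- genomes
  family_of_gene <- character(0)
  for (gi in seq_len(n_gen)) {
    g <- genomes[gi]
    fam_here <- fams[pres[gi, ] == 1L]
    seqs <- vapply(fam_here, function(f)
      paste(mutate_orf(ancestors[[f]], p_within), collapse = ""),
      character(1))
    ids <- sprintf("%s_g%04d", g, seq_along(fam_here))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    genes[[g]] <- dna
    fg <- fam_here; names(fg) <- ids
    family_of_gene <- c(family_of_gene, fg)
  }
  proteins <- lapply(genes, function(x)
    Biostrings::translate(x, if.fuzzy.codon = "error"))

  truth <- list(family_of_gene = family_of_gene,
                lineage_of_genome = lineage_of_genome,
                planted_presence = pres)
  out <- list(genes = genes, proteins = proteins, truth = truth,
              model = model)
  if (!is.null(dir)) write_population(out, dir)
  invisible(out)
}

write_population <- function(pop, dir) {
  dir.create(file.path(dir, "genes"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "proteins"), recursive = TRUE,
             showWarnings = FALSE)
  for (g in names(pop$genes)) {
    write_sequences(pop$genes[[g]], file.path(dir, "genes",
                                              paste0(g, ".fna")))
    write_sequences(pop$proteins[[g]], file.path(dir, "proteins",
                                                 paste0(g, ".faa")))
  }
  tr <- pop$truth
  write.table(data.frame(gene = names(tr$family_of_gene),
                         family = unname(tr$family_of_gene)),
              file.path(dir, "truth_families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(genome = names(tr$lineage_of_genome),
                         lineage = unname(tr$lineage_of_genome)),
              file.path(dir, "truth_lineages.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tr$planted_presence,
              file.path(dir, "truth_presence.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(dir)
}
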