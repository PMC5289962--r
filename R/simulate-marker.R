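#' Marker-locus model: conserved flanks around a variable region
#'
#' Emulates a single-copy enolase-like amplicon target: every allele shares
#' identical 5' and 3' flanks (the primer landing sites) while the variable
#' region in between separates species. Each species receives a dedicated,
#' disjoint set of `min_interspecies_diffs` substituted positions, so any two
#' species' alleles differ at `>= 2 * min_interspecies_diffs` sites;
#' within-species allelic variation never touches planted positions, keeping
#' the inter-species guarantee exact.
#'
#' @param species_labels character vector of species names.
#' @param flank_len conserved flank length in bp (>= intended primer length).
#' @param variable_len variable-region length in bp (default 500).
#' @param min_interspecies_diffs minimum pairwise difference count planted
#'   between species within the variable region.
#' @param intraspecies_divergence per-site substitution probability between
#'   alleles of the same species.
#' @param n_alleles_per_species alleles generated per species.
#' @param seed RNG seed.
#' @return a validated `marker_model` list.
#' @export
marker_model <- function(species_labels = c("Ln_cremoris", "Ln_lactis",
                                            "Ln_mesenteroides",
                                            "Ln_pseudomesenteroides"),
                         flank_len = 25, variable_len = 500,
                         min_interspecies_diffs = 5,
                         intraspecies_divergence = 0.005,
                         n_alleles_per_species = 3, seed = 1) {
  m <- list(species_labels = species_labels, flank_len = flank_len,
            variable_len = variable_len,
            min_interspecies_diffs = min_interspecies_diffs,
            intraspecies_divergence = intraspecies_divergence,
            n_alleles_per_species = n_alleles_per_species, seed = seed)
  assert_that(length(species_labels) >= 2, "need at least two species")
  assert_that(!anyDuplicated(species_labels), "duplicate species labels")
  assert_that(flank_len >= 15, "flanks must be at least 15 bp")
  assert_that(variable_len >= 1, "variable region must be non-empty")
  assert_that(min_interspecies_diffs >= 1, "need at least one planted diff")
  assert_that(length(species_labels) * min_interspecies_diffs <= variable_len,
              "cannot plant ", min_interspecies_diffs, " disjoint diffs for ",
              length(species_labels), " species in ", variable_len, " bp")
  assert_that(intraspecies_divergence >= 0 && intraspecies_divergence < 0.3,
              "intraspecies_divergence must lie in [0, 0.3)")
  assert_that(n_alleles_per_species >= 1, "need at least one allele/species")
  structure(m, class = "marker_model")
}

#' Generate labelled marker alleles
#'
#' @param model a [marker_model()].
#' @param path optional FASTA output path.
#' @return a `DNAStringSet` of alleles; headers carry `species=<label>`.
#' @export
generate_marker_alleles <- function(model, path = NULL) {
  assert_that(inherits(model, "marker_model"),
              "model must come from marker_model()")
  set.seed(model$seed)
  n_sp <- length(model$species_labels)
  flank5 <- random_dna(model$flank_len)
  flank3 <- random_dna(model$flank_len)
  base <- strsplit(random_dna(model$variable_len), "")[[1]]

  planted <- matrix(sample.int(model$variable_len,
                               n_sp * model$min_interspecies_diffs),
                    nrow = n_sp)   # disjoint positions, one row per species
  protos <- lapply(seq_len(n_sp), function(s) {
    v <- base
    pos <- planted[s, ]
    v[pos] <- vapply(v[pos], function(b)
      DNA_BASES[DNA_BASES != b][sample.int(3L, 1L)], character(1),
      USE.NAMES = FALSE)
    v
  })

  free_pos <- setdiff(seq_len(model$variable_len), as.vector(planted))
  seqs <- character(0); headers <- character(0)
  for (s in seq_len(n_sp)) {
    for (a in seq_len(model$n_alleles_per_species)) {
      v <- protos[[s]]
      mut <- free_pos[runif(length(free_pos)) < model$intraspecies_divergence]
      if (length(mut) > 0)
        v[mut] <- vapply(v[mut], function(b)
          DNA_BASES[DNA_BASES != b][sample.int(3L, 1L)], character(1),
          USE.NAMES = FALSE)
      lab <- model$species_labels[s]
      seqs <- c(seqs, paste0(flank5, paste(v, collapse = ""), flank3))
      headers <- c(headers,
                   sprintf("%s_allele%02d species=%s", gsub("\\W", "_", lab),
                           a, lab))
    }
  }
  alleles <- Biostrings::DNAStringSet(seqs)
  names(alleles) <- headers
  attr(alleles, "flanks") <- c(flank5 = flank5, flank3 = flank3)
  if (!is.null(path)) write_sequences(alleles, path)
  alleles
}

#' Species labels of marker alleles
#' @param alleles a `DNAStringSet` whose headers carry `species=<label>`.
#' @return character vector of labels, named by allele ID.
#' @export
allele_species <- function(alleles) {
  sp <- header_field(names(alleles), "species")
  assert_that(!anyNA(sp), "allele(s) without species= header tag: ",
              paste(seq_ids(alleles)[is.na(sp)], collapse = ", "))
  names(sp) <- seq_ids(alleles)
  sp
}
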