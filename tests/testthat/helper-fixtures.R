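# Small, fast fixture builders shared across test files.

small_lineage_model <- function(seed = 1, ...) {
  args <- list(n_lineages = 3, genomes_per_lineage = 2, core_families = 30,
               shared_accessory_pool = 15, lineage_accessory_per_lineage = 8,
               gain_rate = 0, loss_rate = 0,
               gene_length_range = c(90, 150), seed = seed)
  args[names(list(...))] <- list(...)
  do.call(lineage_model, args)
}

small_marker_model <- function(seed = 1, ...) {
  args <- list(species_labels = c("spA", "spB", "spC"), flank_len = 25,
               variable_len = 120, min_interspecies_diffs = 5,
               intraspecies_divergence = 0.005, n_alleles_per_species = 2,
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(marker_model, args)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# quality-scaled read set from plain sequences and integer qualities
qreads <- function(seqs, quals, ids = sprintf("r%02d", seq_along(seqs))) {
  q <- vapply(quals, function(v) intToUtf8(as.integer(v) + 33L),
              character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(q))
  names(x) <- ids
  x
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# hclust-shaped object with prescribed merge heights over n leaves,
# merging left-to-right so only the height sequence matters
fake_tree <- function(heights, labels = NULL) {
  n <- length(heights) + 1L
  labels <- labels %||% sprintf("g%02d", seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  merge[1, ] <- c(-1L, -2L)
  if (n > 2) for (i in 2:(n - 1L)) merge[i, ] <- c(i - 1L, -(i + 1L))
  structure(list(merge = merge, height = sort(heights),
                 order = seq_len(n), labels = labels,
                 method = "complete"),
            class = "hclust")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
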