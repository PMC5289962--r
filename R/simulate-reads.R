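#' Mock-community model for amplicon read simulation
#'
#' Defines a community of known species proportions sequenced as overlapping
#' paired-end amplicon reads with i.i.d. per-base substitution errors and a
#' clipped-normal Phred quality model. Defaults mirror a MiSeq 2 x 300 bp
#' run over a 550 bp amplicon (25 bp flanks + 500 bp variable region) with
#' triplicate libraries.
#'
#' @param proportions named numeric vector of species fractions (sums to 1).
#' @param n_read_pairs read pairs per replicate.
#' @param read_len read length in bp.
#' @param fragment_len amplified fragment length in bp; must not exceed the
#'   amplicon length and must be < 2 * `read_len` so the pair overlaps.
#' @param error_rate per-base substitution probability.
#' @param quality_mean,quality_sd Phred quality model (clipped normal,
#'   bounded to `[2, 41]`).
#' @param replicates number of replicate libraries (default 3).
#' @param seed RNG seed.
#' @return a validated `mock_community` list.
#' @export
mock_community <- function(proportions = c(Ln_cremoris = 0.60,
                                           Ln_pseudomesenteroides = 0.25,
                                           Ln_mesenteroides = 0.15),
                           n_read_pairs = 10000, read_len = 300,
                           fragment_len = 550, error_rate = 0.01,
                           quality_mean = 35, quality_sd = 3,
                           replicates = 3, seed = 1) {
  m <- list(proportions = proportions, n_read_pairs = n_read_pairs,
            read_len = read_len, fragment_len = fragment_len,
            error_rate = error_rate, quality_mean = quality_mean,
            quality_sd = quality_sd, replicates = replicates, seed = seed)
  assert_that(!is.null(names(proportions)) && all(nzchar(names(proportions))),
              "proportions must be named by species")
  assert_that(abs(sum(proportions) - 1) < 1e-8, "proportions must sum to 1")
  assert_that(all(proportions > 0), "proportions must be positive")
  assert_that(n_read_pairs >= 1 && replicates >= 1,
              "need at least one read pair and one replicate")
  assert_that(2 * read_len > fragment_len,
              "reads must overlap: 2 * read_len must exceed fragment_len")
  assert_that(error_rate >= 0 && error_rate < 1,
              "error_rate must lie in [0, 1)")
  structure(m, class = "mock_community")
}

# i.i.d. substitutions over a whole batch of reads at once: reads are
# concatenated into one byte vector, error positions drawn in bulk, and each
# hit base replaced by one of the other three uniformly.
apply_read_errors_batch <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads)
  raw <- charToRaw(paste(reads, collapse = ""))
  idx <- which(runif(length(raw)) < error_rate)
  if (length(idx) > 0) {
    alt <- matrix(c("C", "G", "T",  "A", "G", "T",
                    "A", "C", "T",  "A", "C", "G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(DNA_BASES, NULL))
    cur <- match(rawToChar(raw[idx], multiple = TRUE), DNA_BASES)
    raw[idx] <- charToRaw(paste(
      alt[cbind(cur, sample.int(3L, length(idx), replace = TRUE))],
      collapse = ""))
  }
  big <- rawToChar(raw)
  ends <- cumsum(L)
  substring(big, ends - L + 1L, ends)
}

# batch of clipped-normal Phred quality strings
quality_strings_batch <- function(n, L, mean, sd) {
  q <- pmin(pmax(round(rnorm(n * L, mean, sd)), 2L), 41L)
  big <- intToUtf8(q + 33L)
  ends <- seq_len(n) * L
  substring(big, ends - L + 1L, ends)
}

#' Simulate paired-end amplicon reads from a mock community
#'
#' Template alleles are drawn multinomially by species proportion (uniformly
#' within a species), a fragment of `fragment_len` is excised at a uniform
#' offset, and the pair reads its two ends: R1 on the plus strand, R2
#' reverse-complemented, each with i.i.d. substitution errors at
#' `error_rate` and Phred qualities from the clipped-normal model. Output is
#' deterministic under the community seed.
#'
#' @param community a [mock_community()].
#' @param alleles marker alleles with `species=` header tags (see
#'   [generate_marker_alleles()]).
#' @param dir optional directory; per-replicate
#'   `rep<k>_R1.fastq` / `rep<k>_R2.fastq` files are written there.
#' @return a list with one element per replicate, each holding `r1` and `r2`
#'   (`QualityScaledDNAStringSet`) plus the true template species counts.
#' @export
simulate_amplicon_reads <- function(community, alleles, dir = NULL) {
  assert_that(inherits(community, "mock_community"),
              "community must come from mock_community()")
  sp <- allele_species(alleles)
  want <- names(community$proportions)
  missing <- setdiff(want, unique(sp))
  assert_that(length(missing) == 0,
              "species in proportions without alleles: ",
              paste(missing, collapse = ", "))
  assert_that(community$fragment_len <= min(Biostrings::width(alleles)),
              "fragment_len exceeds the shortest amplicon")
  set.seed(community$seed)
  allele_seq <- as.character(alleles)
  allele_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(alleles)))
  allele_len <- nchar(allele_seq)
  by_species <- split(seq_along(alleles), sp)
  L <- community$read_len
  FLen <- community$fragment_len
  out <- vector("list", community$replicates)
  for (r in seq_len(community$replicates)) {
    n <- community$n_read_pairs
    species_draw <- sample(want, n, replace = TRUE,
                           prob = community$proportions)
    ai <- integer(n)
    for (s in want) {
      pick <- species_draw == s
      ai[pick] <- by_species[[s]][sample.int(length(by_species[[s]]),
                                             sum(pick), replace = TRUE)]
    }
    # uniform fragment offset, then the two fragment ends as reads; R2 is
    # the last read_len of the fragment on the minus strand
    off <- floor(runif(n) * (allele_len[ai] - FLen + 1L))
    r1 <- substring(allele_seq[ai], off + 1L, off + L)
    rc_off <- allele_len[ai] - off - FLen      # fragment end, minus strand
    r2 <- substring(allele_rc[ai], rc_off + 1L, rc_off + L)
    r1 <- apply_read_errors_batch(r1, community$error_rate)
    r2 <- apply_read_errors_batch(r2, community$error_rate)
    q1 <- quality_strings_batch(n, L, community$quality_mean,
                                community$quality_sd)
    q2 <- quality_strings_batch(n, L, community$quality_mean,
                                community$quality_sd)
    ids <- sprintf("rep%d_read%05d", r, seq_len(n))
    mk <- function(s, q) {
      x <- Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(s), Biostrings::PhredQuality(q))
      names(x) <- ids
      x
    }
    out[[r]] <- list(r1 = mk(r1, q1), r2 = mk(r2, q2),
                     true_counts = table(factor(species_draw,
                                                levels = want)))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_sequences(out[[r]]$r1,
                      file.path(dir, sprintf("rep%d_R1.fastq", r)))
      write_sequences(out[[r]]$r2,
                      file.path(dir, sprintf("rep%d_R2.fastq", r)))
    }
  }
  names(out) <- sprintf("rep%d", seq_len(community$replicates))
  invisible(out)
}
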