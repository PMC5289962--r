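#' Parameters for ortholog clustering
#'
#' @param inflation MCL inflation (granularity) parameter; must be > 1.
#' @param min_identity minimum alignment identity for a similarity edge.
#' @param min_coverage minimum aligned fraction of the shorter sequence.
#' @param gap_open,gap_extend affine gap penalties (BLOSUM62 scoring; a gap
#'   of length k costs `gap_open + k * gap_extend`).
#' @param kmer_len,kmer_stride,max_kmer_bucket amino-acid k-mer prefilter:
#'   only gene pairs sharing at least `min_shared_kmers` sampled k-mers are
#'   aligned; buckets larger than `max_kmer_bucket` (low-complexity k-mers)
#'   are skipped.
#' @param min_shared_kmers see above.
#' @param band_extra Smith-Waterman band half-width beyond the length
#'   difference; negative disables banding.
#' @param max_mcl_iters,convergence_tol MCL iteration control.
#' @param singleton_curation_identity,singleton_length_deviation curation
#'   rule: a singleton is dropped when its best hit identity is below the
#'   first AND its length deviates from that hit by more than the second
#'   (fraction).
#' @param singleton_hit_coverage minimum aligned fraction of the shorter
#'   sequence for a sub-threshold hit to count during singleton curation.
#' @return a validated `clustering_params` list.
#' @export
clustering_params <- function(inflation = 1.5, min_identity = 0.30,
                              min_coverage = 0.75, gap_open = 11,
                              gap_extend = 1, kmer_len = 5, kmer_stride = 7,
                              min_shared_kmers = 1, max_kmer_bucket = 500,
                              band_extra = 24, max_mcl_iters = 200,
                              convergence_tol = 1e-6,
                              singleton_curation_identity = 0.5,
                              singleton_length_deviation = 0.5,
                              singleton_hit_coverage = 0.3) {
  p <- as.list(environment())
  assert_that(inflation > 1, "inflation must be > 1")
  assert_that(min_identity > 0 && min_identity <= 1 &&
                min_coverage > 0 && min_coverage <= 1,
              "identity/coverage thresholds must lie in (0, 1]")
  assert_that(convergence_tol > 0 && max_mcl_iters >= 1,
              "invalid MCL iteration control")
  structure(p, class = "clustering_params")
}

pkg_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  pkg_cache$BLOSUM62
}

# BLOSUM62 as a 128 x 128 lookup indexed by raw char code, for the C++ kernel.
char_submat <- function(mat) {
  out <- matrix(-4L, 128, 128)
  codes <- utf8ToInt(paste(rownames(mat), collapse = ""))
  out[codes + 1, codes + 1] <- as.integer(mat)
  out
}

self_scores <- function(seqs, mat) {
  diag_score <- diag(mat)
  vapply(strsplit(as.character(seqs), ""), function(ch)
    sum(diag_score[ch]), numeric(1))
}

# Candidate gene pairs sharing >= min_shared sampled k-mers.
kmer_candidate_pairs <- function(seqs, k, stride, min_shared, max_bucket) {
  n <- length(seqs)
  chars <- as.character(seqs)
  kmers_of <- lapply(chars, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq(1L, L - k + 1L, by = stride)
    unique(substring(s, starts, starts + k - 1L))
  })
  idx <- rep(seq_len(n), lengths(kmers_of))
  buckets <- split(idx, unlist(kmers_of))
  pair_keys <- lapply(buckets, function(v) {
    v <- sort.int(unique(v))
    m <- length(v)
    if (m < 2L || m > max_bucket) return(numeric(0))
    i <- rep(v[-m], times = (m - 1L):1L)
    j <- v[sequence((m - 1L):1L, from = 2L:m)]
    (i - 1) * n + j
  })
  keys <- unlist(pair_keys, use.names = FALSE)
  if (length(keys) == 0) return(cbind(integer(0), integer(0)))
  if (min_shared > 1) {
    tab <- table(keys)
    keys <- as.numeric(names(tab)[tab >= min_shared])
  } else keys <- unique(keys)
  keys <- sort(keys)
  cbind(as.integer((keys - 1) %/% n) + 1L, as.integer((keys - 1) %% n) + 1L)
}

#' All-against-all protein similarity edges
#'
#' Aligns candidate gene pairs with banded affine-gap Smith-Waterman
#' (BLOSUM62) and emits an undirected edge whenever alignment identity and
#' coverage (aligned fraction of the shorter sequence) pass their gates.
#' The edge score is the raw alignment score normalized by the
#' self-alignment score of the shorter sequence, so identical sequences
#' score exactly 1. A sampled k-mer prefilter avoids aligning the vast
#' majority of unrelated pairs; it is a speed heuristic and can be disabled
#' by setting `kmer_stride` and `min_shared_kmers` to 1 with a large bucket
#' cap.
#'
#' @param proteomes named list (genome -> `AAStringSet` of proteins); gene
#'   IDs must be globally unique.
#' @param params a [clustering_params()].
#' @return data.frame with columns `gene_a`, `gene_b`, `genome_a`,
#'   `genome_b`, `score`, `identity`, `coverage`; one row per unordered pair.
#'   The full gene table is attached as attribute `genes`.
#' @export
all_vs_all_similarity <- function(proteomes, params = clustering_params()) {
  assert_that(length(proteomes) >= 2, "need at least two genomes")
  empty <- names(proteomes)[lengths(proteomes) == 0]
  assert_that(length(empty) == 0, "empty proteome for genome(s): ",
              paste(empty, collapse = ", "))
  all_seqs <- do.call(c, unname(lapply(proteomes, function(x) {
    y <- Biostrings::AAStringSet(x); names(y) <- seq_ids(x); y
  })))
  genome_of <- rep(names(proteomes), times = lengths(proteomes))
  ids <- names(all_seqs)
  assert_that(!anyDuplicated(ids), "gene IDs must be globally unique")
  names(genome_of) <- ids

  pairs <- kmer_candidate_pairs(all_seqs, params$kmer_len,
                                params$kmer_stride,
                                params$min_shared_kmers,
                                params$max_kmer_bucket)
  genes_attr <- data.frame(gene = ids, genome = unname(genome_of),
                           length = Biostrings::width(all_seqs),
                           stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0),
                      genome_a = character(0), genome_b = character(0),
                      score = numeric(0), identity = numeric(0),
                      coverage = numeric(0), stringsAsFactors = FALSE)
    attr(out, "genes") <- genes_attr
    return(out)
  }
  mat <- char_submat(blosum62())
  stats <- sw_stats_batch(as.character(all_seqs[pairs[, 1]]),
                          as.character(all_seqs[pairs[, 2]]),
                          mat, params$gap_open, params$gap_extend,
                          params$band_extra)
  wa <- Biostrings::width(all_seqs)[pairs[, 1]]
  wb <- Biostrings::width(all_seqs)[pairs[, 2]]
  shorter <- pmin(wa, wb)
  identity <- ifelse(stats$aln_cols > 0, stats$matches / stats$aln_cols, 0)
  span_short <- ifelse(wa <= wb, stats$span_a, stats$span_b)
  coverage <- span_short / shorter
  selfs <- self_scores(all_seqs, blosum62())
  self_short <- ifelse(wa <= wb, selfs[pairs[, 1]], selfs[pairs[, 2]])
  score <- stats$score / self_short
  keep <- identity >= params$min_identity & coverage >= params$min_coverage &
    score > 0
  a <- ids[pairs[keep, 1]]; b <- ids[pairs[keep, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b,
                    genome_a = unname(genome_of[a]),
                    genome_b = unname(genome_of[b]),
                    score = pmin(score[keep], 1), identity = identity[keep],
                    coverage = pmin(coverage[keep], 1),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genes") <- genes_attr
  # sub-threshold search hits, kept for singleton curation
  hit <- score > 0 & !keep
  attr(out, "hits") <- data.frame(
    gene_a = ids[pairs[hit, 1]], gene_b = ids[pairs[hit, 2]],
    score = score[hit], identity = identity[hit],
    coverage = pmin(coverage[hit], 1), stringsAsFactors = FALSE)
  out
}
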