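#' Dereplicate reads at 100% identity
#'
#' Exact full-length, case-normalized string grouping. Output is sorted by
#' abundance (descending), ties broken lexicographically by sequence.
#'
#' @param reads a `filtered_reads` object, `QualityScaledDNAStringSet`,
#'   `DNAStringSet`, or character vector.
#' @return data.frame of class `unique_sequences` with columns `seq`,
#'   `abundance`, and list-column `member_read_ids`.
#' @export
dereplicate <- function(reads) {
  if (inherits(reads, "filtered_reads")) reads <- reads$reads
  seqs <- toupper(as.character(reads))
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  if (is.null(names(seqs)) || any(!nzchar(ids)))
    ids <- as.character(seq_along(seqs))
  groups <- split(ids, seqs)
  out <- data.frame(seq = names(groups),
                    abundance = lengths(groups),
                    stringsAsFactors = FALSE)
  out$member_read_ids <- unname(groups)
  out <- out[order(-out$abundance, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("unique_sequences", "data.frame")
  out
}

#' Denoise unique sequences by abundance-skew absorption
#'
#' Greedy pass in abundance order: each sequence becomes a centroid unless
#' it lies within `denoise_max_diffs` substitutions of an existing centroid
#' whose current abundance is at least `denoise_abundance_skew` times its
#' own, in which case its abundance is absorbed into that centroid (the
#' most abundant eligible one). Centroids still at abundance 1 afterwards
#' are discarded when `discard_singletons` is set.
#'
#' @param uniques a `unique_sequences` data.frame from [dereplicate()].
#' @param params a [quant_params()].
#' @return data.frame of class `unique_sequences` (centroids) with columns
#'   `seq`, `abundance` (absorbed totals) and `n_absorbed` variants; the
#'   number of reads discarded with singletons is kept in attribute
#'   `n_discarded_reads`.
#' @export
denoise <- function(uniques, params = quant_params()) {
  assert_that(inherits(uniques, "unique_sequences"),
              "uniques must come from dereplicate()")
  n <- nrow(uniques)
  cent_seq <- character(n); cent_ab <- numeric(n); cent_n <- integer(n)
  nc <- 0L
  max_d <- as.integer(params$denoise_max_diffs)
  skew <- params$denoise_abundance_skew
  for (i in seq_len(n)) {
    s <- uniques$seq[i]; a <- uniques$abundance[i]
    absorbed <- FALSE
    if (nc > 0L && max_d > 0) {
      # only centroids clearing the abundance-skew gate can absorb
      eligible <- which(cent_ab[seq_len(nc)] >= skew * a)
      if (length(eligible) > 0) {
        d <- hamming_bounded(s, cent_seq[eligible], max_d)
        hit <- eligible[d <= max_d]
        if (length(hit) > 0) {
          tgt <- hit[which.max(cent_ab[hit])]
          cent_ab[tgt] <- cent_ab[tgt] + a
          cent_n[tgt] <- cent_n[tgt] + 1L
          absorbed <- TRUE
        }
      }
    }
    if (!absorbed) {
      nc <- nc + 1L
      cent_seq[nc] <- s; cent_ab[nc] <- a; cent_n[nc] <- 0L
    }
  }
  cent_seq <- cent_seq[seq_len(nc)]; cent_ab <- cent_ab[seq_len(nc)]
  cent_n <- cent_n[seq_len(nc)]
  keep <- if (params$discard_singletons) cent_ab > 1 else
    rep(TRUE, length(cent_ab))
  out <- data.frame(seq = cent_seq[keep], abundance = cent_ab[keep],
                    n_absorbed = cent_n[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("unique_sequences", "data.frame")
  attr(out, "n_discarded_reads") <- sum(cent_ab[!keep])
  out
}
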