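#' Center-star multiple alignment of a gene family
#'
#' Pairwise global alignments use match +1, mismatch -1, linear gap -2. The
#' center is the sequence maximizing the summed pairwise alignment score to
#' all others; every other sequence is aligned to the center and the
#' pairwise alignments are merged under "once a gap, always a gap" (gaps
#' inserted into the center accumulate across alignments; insertion blocks
#' are left-justified).
#'
#' @param seqs a `DNAStringSet` (>= 2 sequences) of one gene family.
#' @return named character vector of equal-length gapped rows (class
#'   `center_star_msa`), in input order, with the center ID in attribute
#'   `center`.
#' @export
align_cluster <- function(seqs) {
  assert_that(length(seqs) >= 1, "empty input")
  ids <- seq_ids(seqs)
  assert_that(!anyDuplicated(ids), "duplicate sequence IDs")
  if (length(seqs) == 1) {
    out <- structure(as.character(seqs), names = ids,
                     class = "center_star_msa")
    attr(out, "center") <- ids[1]
    return(out)
  }
  n <- length(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  # an infinitesimal surcharge on the linear gap cost (-2) resolves exact
  # score ties between gapped and ungapped optima toward the ungapped one
  gap_ext <- 2 + 1e-6
  score_sum <- numeric(n)
  for (i in seq_len(n - 1)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(Biostrings::DNAStringSet(seqs[i]), n - i),
      Biostrings::DNAStringSet(seqs[(i + 1):n]),
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = gap_ext)
    sc <- Biostrings::score(aln)
    score_sum[i] <- score_sum[i] + sum(sc)
    score_sum[(i + 1):n] <- score_sum[(i + 1):n] + sc
  }
  ci <- which.max(score_sum)
  center <- Biostrings::DNAStringSet(seqs[ci])
  others <- setdiff(seq_len(n), ci)
  Lc <- Biostrings::width(center)

  # per-alignment center-gap profiles and per-sequence pieces
  ins_after <- matrix(0L, length(others), Lc + 1L)
  pieces <- vector("list", length(others))
  for (oi in seq_along(others)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs[others[oi]]), center,
      type = "global", substitutionMatrix = mat,
      gapOpening = 0, gapExtension = gap_ext)
    cg <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    og <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    cpos <- cumsum(cg != "-")
    blocks <- vector("list", Lc + 1L)   # insertions after center pos 0..Lc
    at_pos <- character(Lc)
    for (col in seq_along(cg)) {
      if (cg[col] == "-") {
        slot <- cpos[col] + 1L
        blocks[[slot]] <- c(blocks[[slot]], og[col])
      } else at_pos[cpos[col]] <- og[col]
    }
    ins_after[oi, ] <- vapply(blocks, length, integer(1))
    pieces[[oi]] <- list(blocks = blocks, at_pos = at_pos)
  }
  master_ins <- if (length(others) > 0) apply(ins_after, 2, max)
  else integer(Lc + 1L)

  center_chars <- strsplit(as.character(center), "")[[1]]
  build_row <- function(blocks, at_pos) {
    out <- character(0)
    for (p in 0:Lc) {
      blk <- blocks[[p + 1L]] %||% character(0)
      out <- c(out, blk, rep("-", master_ins[p + 1L] - length(blk)))
      if (p < Lc) out <- c(out, at_pos[p + 1L])
    }
    paste(out, collapse = "")
  }
  rows <- character(n)
  rows[ci] <- build_row(vector("list", Lc + 1L), center_chars)
  for (oi in seq_along(others))
    rows[others[oi]] <- build_row(pieces[[oi]]$blocks, pieces[[oi]]$at_pos)
  names(rows) <- ids
  structure(rows, class = "center_star_msa", center = ids[ci])
}

msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Per-column conservation profile of an alignment
#'
#' @param aln a gapped alignment: named character vector of equal-length
#'   rows (e.g. from [align_cluster()]).
#' @return list of class `conservation_profile`: `consensus_frac` (modal
#'   non-gap symbol count / number of rows), `gap_frac`, and the consensus
#'   string (modal non-gap symbol, alphabetic tie-break; `-` for all-gap
#'   columns).
#' @export
conservation_profile <- function(aln) {
  m <- msa_matrix(aln)
  assert_that(length(unique(nchar(unclass(aln)))) == 1L,
              "alignment rows must have equal length")
  n <- nrow(m)
  cons_frac <- numeric(ncol(m)); gap_frac <- numeric(ncol(m))
  consensus <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gaps <- col == "-"
    gap_frac[j] <- mean(gaps)
    if (all(gaps)) { consensus[j] <- "-"; cons_frac[j] <- 0; next }
    tab <- table(col[!gaps])
    cons_frac[j] <- max(tab) / n
    consensus[j] <- sort(names(tab)[tab == max(tab)])[1]
  }
  structure(list(consensus_frac = cons_frac, gap_frac = gap_frac,
                 consensus = paste(consensus, collapse = "")),
            class = "conservation_profile")
}
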