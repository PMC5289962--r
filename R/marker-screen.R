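#' Parameters for the amplicon-marker screen
#'
#' @param window_len variable-region window length in bp (default 500).
#' @param flank_len conserved flank length required on each side (default
#'   25 bp, enough to land a primer).
#' @param flank_min_consensus minimum per-column consensus fraction in the
#'   flanks (default 1 = perfect conservation, since primers must match
#'   every species).
#' @param min_interspecies_diffs minimum pairwise difference count between
#'   members of different species inside the window.
#' @param max_offtarget_identity candidates whose window matches an
#'   off-target at or above this identity are rejected.
#' @param max_primer_mismatches mismatch tolerance for primer-site matching.
#' @return a validated `screen_params` list.
#' @export
screen_params <- function(window_len = 500, flank_len = 25,
                          flank_min_consensus = 1.0,
                          min_interspecies_diffs = 5,
                          max_offtarget_identity = 0.85,
                          max_primer_mismatches = 2) {
  p <- as.list(environment())
  assert_that(flank_len >= 1 && window_len > flank_len,
              "flank_len must be positive and smaller than window_len")
  assert_that(flank_min_consensus > 0 && flank_min_consensus <= 1,
              "flank_min_consensus must lie in (0, 1]")
  assert_that(max_offtarget_identity > 0 && max_offtarget_identity <= 1,
              "max_offtarget_identity must lie in (0, 1]")
  structure(p, class = "screen_params")
}

#' Scan an aligned gene family for amplicon candidate windows
#'
#' Slides a `window_len` window over the alignment. A placement qualifies
#' when (a) the `flank_len` columns abutting each end of the window are
#' gap-free with consensus fraction at or above `flank_min_consensus`, and
#' (b) every pair of sequences from different species differs at
#' `>= min_interspecies_diffs` columns inside the window. Qualifying
#' windows are ranked by that minimum inter-species difference count
#' (descending), then by window variability (mean 1 - consensus fraction),
#' then leftmost. Because consecutive placements over the same locus all
#' qualify together, overlapping windows are coalesced by default: the
#' best-ranked placement is kept and every qualifying window overlapping it
#' is dropped, so each reported candidate is one distinct amplicon region.
#' The primer pair is the 5' flank consensus (forward) and the reverse
#' complement of the 3' flank consensus.
#'
#' @param profile a [conservation_profile()] of the alignment.
#' @param aln the alignment itself (see [align_cluster()]).
#' @param groups named character vector: sequence ID -> species label.
#' @param params a [screen_params()].
#' @param og_id identifier of the gene family, copied into the output.
#' @param coalesce drop qualifying windows overlapping a better-ranked one
#'   (default `TRUE`).
#' @return data.frame of ranked candidates (possibly empty = gene
#'   excluded): window and flank intervals in 0-based half-open alignment
#'   coordinates, the same window in ungapped coordinates of the first
#'   sequence, `discrimination`, `variability`, primers, and the window
#'   consensus.
#' @export
scan_candidate_windows <- function(profile, aln, groups,
                                   params = screen_params(),
                                   og_id = NA_character_, coalesce = TRUE) {
  m <- msa_matrix(aln)
  L <- ncol(m)
  ids <- rownames(m)
  assert_that(all(ids %in% names(groups)),
              "sequences without a species label: ",
              paste(setdiff(ids, names(groups)), collapse = ", "))
  grp <- groups[ids]
  W <- params$window_len; FL <- params$flank_len
  empty <- data.frame(og_id = character(0), win_start = integer(0),
                      win_end = integer(0), flank5_start = integer(0),
                      flank3_end = integer(0), rep_start = integer(0),
                      rep_end = integer(0), discrimination = integer(0),
                      variability = numeric(0), primer_fwd = character(0),
                      primer_rev = character(0),
                      window_consensus = character(0),
                      stringsAsFactors = FALSE)
  if (L < W + 2 * FL || length(unique(grp)) < 2) return(empty)

  col_ok <- profile$consensus_frac >= params$flank_min_consensus &
    profile$gap_frac == 0
  ok_cum <- c(0, cumsum(col_ok))
  all_ok <- function(from, to) ok_cum[to + 1] - ok_cum[from] == to - from + 1

  pairs <- which(outer(grp, grp, "!=") & upper.tri(diag(length(ids))),
                 arr.ind = TRUE)
  diff_cum <- apply(pairs, 1, function(pr)
    c(0, cumsum(m[pr[1], ] != m[pr[2], ])))
  var_cum <- c(0, cumsum(1 - profile$consensus_frac))

  starts <- seq_len(L - W - 2 * FL + 1) + FL   # 1-based window starts
  cons <- strsplit(profile$consensus, "")[[1]]
  rep_map <- cumsum(m[1, ] != "-")
  rows <- list()
  for (s in starts) {
    if (!all_ok(s - FL, s - 1) || !all_ok(s + W, s + W + FL - 1)) next
    disc <- min(diff_cum[s + W, ] - diff_cum[s, ])
    if (disc < params$min_interspecies_diffs) next
    rows[[length(rows) + 1]] <- data.frame(
      og_id = og_id,
      win_start = s - 1L, win_end = s + W - 1L,
      flank5_start = s - FL - 1L, flank3_end = s + W + FL - 1L,
      rep_start = rep_map[s] - as.integer(m[1, s] != "-"),
      rep_end = rep_map[s + W - 1L],
      discrimination = as.integer(disc),
      variability = (var_cum[s + W] - var_cum[s]) / W,
      primer_fwd = paste(cons[(s - FL):(s - 1)], collapse = ""),
      primer_rev = as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(cons[(s + W):(s + W + FL - 1)],
                                    collapse = "")))),
      window_consensus = gsub("-", "", paste(cons[s:(s + W - 1)],
                                             collapse = "")),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(-out$discrimination, -out$variability, out$win_start), ,
             drop = FALSE]
  if (coalesce && nrow(out) > 1) {
    taken <- logical(0); starts <- integer(0); ends <- integer(0)
    keep <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      overlaps <- any(out$win_start[i] < ends & out$win_end[i] > starts)
      if (!overlaps) {
        keep[i] <- TRUE
        starts <- c(starts, out$win_start[i])
        ends <- c(ends, out$win_end[i])
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

strand_hits <- function(pattern, subject, max_mismatch) {
  p <- Biostrings::DNAString(pattern)
  fwd <- Biostrings::countPattern(p, subject, max.mismatch = max_mismatch,
                                  fixed = FALSE) > 0
  rev <- Biostrings::countPattern(Biostrings::reverseComplement(p), subject,
                                  max.mismatch = max_mismatch,
                                  fixed = FALSE) > 0
  fwd || rev
}

#' Reject amplicon candidates that cross-react with off-target sequences
#'
#' A candidate is removed when, for any off-target sequence, both of its
#' primers match (either strand) within `max_primer_mismatches`, or its
#' window consensus aligns to the off-target at identity
#' `>= max_offtarget_identity`. This mirrors discarding loci whose primer
#' sites or amplified region also occur in non-target dairy organisms.
#'
#' @param cands candidate data.frame from [scan_candidate_windows()].
#' @param offtargets a `DNAStringSet` of off-target sequences (e.g.
#'   lactococcal homologs).
#' @param params a [screen_params()].
#' @return the filtered data.frame; removals with reasons are kept in
#'   attribute `removed`.
#' @export
offtarget_filter <- function(cands, offtargets, params = screen_params()) {
  if (nrow(cands) == 0) return(cands)
  keep <- logical(nrow(cands))
  reasons <- character(0)
  for (i in seq_len(nrow(cands))) {
    reason <- NA_character_
    win <- Biostrings::DNAString(cands$window_consensus[i])
    rev_rc <- Biostrings::reverseComplement(
      Biostrings::DNAString(cands$primer_rev[i]))
    for (oi in seq_along(offtargets)) {
      ot <- offtargets[[oi]]
      both <- strand_hits(cands$primer_fwd[i], ot,
                          params$max_primer_mismatches) &&
        strand_hits(as.character(rev_rc), ot, params$max_primer_mismatches)
      if (both) {
        reason <- paste0("both primers match ", seq_ids(offtargets)[oi])
        break
      }
      ident <- max(offtarget_identity(win, ot),
                   offtarget_identity(win,
                                      Biostrings::reverseComplement(ot)))
      if (ident >= params$max_offtarget_identity) {
        reason <- sprintf("window identity %.2f to %s", ident,
                          seq_ids(offtargets)[oi])
        break
      }
    }
    keep[i] <- is.na(reason)
    if (!is.na(reason))
      reasons <- c(reasons, sprintf("%s[%d]: %s", cands$og_id[i],
                                    cands$win_start[i], reason))
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- reasons
  out
}

# Identity of a window fitted locally into an off-target sequence.
offtarget_identity <- function(window, offtarget) {
  aln <- Biostrings::pairwiseAlignment(window, offtarget,
                                       type = "global-local")
  Biostrings::nmatch(aln) / length(window)
}

#' A primer pair
#'
#' @param forward,reverse primer sequences 5'->3' as synthesized (IUPAC
#'   codes allowed); the reverse primer anneals to the plus strand as its
#'   reverse complement.
#' @param max_mismatches per-primer mismatch tolerance when locating sites.
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(forward, reverse, max_mismatches = 2) {
  assert_that(nzchar(forward) && nzchar(reverse),
              "primers must be non-empty")
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = max_mismatches), class = "primer_pair")
}

#' The published enolase (eno) primer pair Eno-F / Eno-R
#'
#' The Leuconostoc-specific primers flanking the eno variable region used
#' for species quantification in starter cultures.
#'
#' @param max_mismatches per-primer mismatch tolerance.
#' @return a [primer_pair()].
#' @export
eno_primers <- function(max_mismatches = 2) {
  primer_pair("AACACGAAGCTGTTGAATTGCGTG",
              "GCAAATCCACCTTCATCACCAACTGA", max_mismatches)
}

#' Locate the amplicon a primer pair would produce on a template
#'
#' Finds the forward primer on the plus strand and the reverse primer's
#' reverse complement strictly downstream of it, each with at most
#' `max_mismatches` mismatches under IUPAC-aware matching. Returns the
#' outermost, primer-inclusive interval (0-based, half-open); the leftmost
#' amplicon wins ties among overlapping hits, while multiple
#' *non-overlapping* amplicons raise an error to force an explicit choice.
#'
#' @param template an ungapped `DNAString`/`DNAStringSet` element or
#'   character string.
#' @param primers a [primer_pair()].
#' @return list(`start`, `end`, `length`, `seq`) or `NULL` when no amplicon
#'   is found.
#' @export
locate_primers <- function(template, primers) {
  assert_that(inherits(primers, "primer_pair"),
              "primers must come from primer_pair()")
  tmpl <- if (is(template, "DNAString")) template
  else Biostrings::DNAString(as.character(template)[1])
  assert_that(!grepl("-", as.character(tmpl)), "template must be ungapped")
  mm <- primers$max_mismatches
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(primers$forward),
                                     tmpl, max.mismatch = mm, fixed = FALSE)
  r_hits <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse)),
    tmpl, max.mismatch = mm, fixed = FALSE)
  if (length(f_hits) == 0 || length(r_hits) == 0) return(NULL)
  fs <- IRanges::start(f_hits); fe <- IRanges::end(f_hits)
  rs <- IRanges::start(r_hits); re <- IRanges::end(r_hits)
  amps <- list()
  for (i in seq_along(fs)) for (j in seq_along(rs)) {
    if (rs[j] > fe[i]) amps[[length(amps) + 1]] <- c(fs[i], re[j])
  }
  if (length(amps) == 0) return(NULL)
  amps <- unique(do.call(rbind, amps))
  amps <- amps[order(amps[, 1], amps[, 2]), , drop = FALSE]
  if (nrow(amps) > 1) {
    disjoint <- any(amps[-1, 1] > amps[1, 2])
    if (disjoint)
      abort("multiple non-overlapping amplicons: ",
            paste(sprintf("[%d,%d)", amps[, 1] - 1L, amps[, 2]),
                  collapse = " "), "; restrict the template or primers")
  }
  hit <- amps[1, ]
  list(start = hit[1] - 1L, end = hit[2], length = hit[2] - hit[1] + 1L,
       seq = as.character(Biostrings::subseq(tmpl, hit[1], hit[2])))
}
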