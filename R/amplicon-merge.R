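#' Parameters for the amplicon quantification pipeline
#'
#' @param min_overlap minimum read-pair overlap in bp.
#' @param max_overlap_mismatch_frac maximum mismatch fraction tolerated in
#'   the chosen overlap.
#' @param max_expected_errors expected-errors ceiling for the quality
#'   filter (sum of per-base error probabilities).
#' @param min_mean_q mean-quality threshold for the alternative
#'   `"mean_q"` filter.
#' @param denoise_max_diffs maximum substitutions for a variant to be
#'   absorbed into a centroid.
#' @param denoise_abundance_skew minimum centroid/variant abundance ratio
#'   for absorption.
#' @param discard_singletons drop abundance-1 centroids after denoising
#'   (off by default: abundance here is aggregated by reference
#'   classification, not de-novo OTU calling, so singletons carry real
#'   signal and discarding them biases composition against low-abundance
#'   species).
#' @param min_classify_identity minimum global-alignment identity for a
#'   species assignment.
#' @return a validated `quant_params` list.
#' @export
quant_params <- function(min_overlap = 20, max_overlap_mismatch_frac = 0.1,
                         max_expected_errors = 1.0, min_mean_q = 20,
                         denoise_max_diffs = 1, denoise_abundance_skew = 8,
                         discard_singletons = FALSE,
                         min_classify_identity = 0.97) {
  p <- as.list(environment())
  assert_that(min_overlap >= 1, "min_overlap must be positive")
  assert_that(max_overlap_mismatch_frac > 0 &&
                max_overlap_mismatch_frac <= 1,
              "max_overlap_mismatch_frac must lie in (0, 1]")
  assert_that(max_expected_errors > 0, "max_expected_errors must be > 0")
  assert_that(denoise_max_diffs >= 0 && denoise_abundance_skew > 0,
              "invalid denoising parameters")
  assert_that(min_classify_identity > 0 && min_classify_identity <= 1,
              "min_classify_identity must lie in (0, 1]")
  structure(p, class = "quant_params")
}

#' Merge paired-end amplicon reads
#'
#' R2 is reverse-complemented and the suffix-prefix overlap with the best
#' +1/-1 score among overlaps of at least `min_overlap` bp is chosen (ties
#' go to the longer overlap). A pair is merged when the mismatch fraction
#' inside that overlap is at most `max_overlap_mismatch_frac`; consensus
#' bases take the agreeing base with quality `max(q1, q2)`, conflicts take
#' the higher-quality base with quality `|q1 - q2|`.
#'
#' @param r1,r2 `QualityScaledDNAStringSet` of equal length; R2 in
#'   sequencing orientation (reverse strand).
#' @param params a [quant_params()].
#' @return list of class `merged_reads`: `reads` (merged
#'   `QualityScaledDNAStringSet`), `stats` (per-pair data.frame with
#'   `overlap`, `mismatches`, `accepted`), and `n_input` / `n_merged` /
#'   `n_unmerged` counts.
#' @export
merge_pairs <- function(r1, r2, params = quant_params()) {
  assert_that(length(r1) == length(r2), "r1 and r2 must pair up")
  assert_that(is(r1, "QualityScaledXStringSet") &&
                is(r2, "QualityScaledXStringSet"),
              "reads must carry qualities (read FASTQ input)")
  r2rc <- Biostrings::reverseComplement(r2)
  res <- merge_pairs_cpp(as.character(r1), as.character(r2rc),
                         phred_scores(r1), phred_scores(r2rc),
                         as.integer(params$min_overlap),
                         params$max_overlap_mismatch_frac)
  ok <- res$accepted
  merged <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(as.character(res$seq)[ok]),
    Biostrings::PhredQuality(vapply(res$qual[ok], phred_to_string,
                                    character(1))))
  names(merged) <- seq_ids(r1)[ok]
  stats <- data.frame(id = seq_ids(r1), overlap = res$overlap,
                      mismatches = res$mismatches, accepted = ok,
                      stringsAsFactors = FALSE)
  structure(list(reads = merged, stats = stats, n_input = length(r1),
                 n_merged = sum(ok), n_unmerged = sum(!ok)),
            class = "merged_reads")
}

#' Quality-filter merged reads by expected errors
#'
#' Keeps a read iff its expected error count `sum(10^(-q/10))` is at most
#' `max_expected_errors` (standard for amplicon data), or — with
#' `method = "mean_q"` — iff its mean Phred quality is at least
#' `min_mean_q`.
#'
#' @param merged a `merged_reads` object from [merge_pairs()] or a
#'   `QualityScaledDNAStringSet`.
#' @param params a [quant_params()].
#' @param method `"expected_errors"` (default) or `"mean_q"`.
#' @return list of class `filtered_reads`: `reads`, `n_input`, `n_kept`,
#'   `n_discarded`, `expected_errors` (per input read).
#' @export
quality_filter <- function(merged, params = quant_params(),
                           method = c("expected_errors", "mean_q")) {
  method <- match.arg(method)
  reads <- if (inherits(merged, "merged_reads")) merged$reads else merged
  q <- phred_scores(reads)
  ee <- vapply(q, function(v) sum(10^(-v / 10)), numeric(1))
  keep <- if (method == "expected_errors") ee <= params$max_expected_errors
  else vapply(q, mean, numeric(1)) >= params$min_mean_q
  structure(list(reads = reads[keep], n_input = length(reads),
                 n_kept = sum(keep), n_discarded = sum(!keep),
                 expected_errors = ee),
            class = "filtered_reads")
}
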