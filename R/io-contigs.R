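#' Fold-coverage of assembled contigs
#'
#' Coverage is taken from SPAdes-style header tokens (`..._cov_12.3`) when
#' present; otherwise a two-column sidecar table (`contig_id`, `coverage`)
#' supplies it. The value is treated as opaque fold-coverage — whatever
#' statistic the assembler reported.
#'
#' @param contigs a `DNAStringSet` of contigs.
#' @param sidecar optional path to (or data.frame of) a headerless two-column
#'   TSV mapping contig ID to coverage.
#' @return numeric vector of coverages, named by contig ID.
#' @export
contig_coverage <- function(contigs, sidecar = NULL) {
  ids <- seq_ids(contigs)
  cov <- suppressWarnings(as.numeric(
    sub("^.*cov_([0-9.eE+-]+).*$", "\\1", names(contigs))))
  cov[!grepl("cov_", names(contigs))] <- NA_real_
  if (!is.null(sidecar)) {
    tab <- if (is.data.frame(sidecar)) sidecar else
      read.table(sidecar, sep = "\t", header = FALSE,
                 col.names = c("contig_id", "coverage"),
                 stringsAsFactors = FALSE)
    idx <- match(ids, tab[[1]])
    cov[!is.na(idx)] <- tab[[2]][idx[!is.na(idx)]]
  }
  missing <- ids[is.na(cov)]
  if (length(missing) > 0)
    abort("no coverage annotation for contig(s): ",
          paste(missing, collapse = ", "))
  assert_that(all(cov >= 0), "negative coverage value(s)")
  names(cov) <- ids
  cov
}

#' Remove short or low-coverage contigs
#'
#' Keeps exactly the contigs with length >= `min_len` and coverage >=
#' `min_cov`, preserving input order, so a 999 bp contig is dropped while a
#' 1000 bp contig at 5x coverage is kept. Idempotent by construction.
#'
#' @param contigs a `DNAStringSet` of contigs.
#' @param min_len minimum length in bp (default 1000).
#' @param min_cov minimum fold coverage (default 5).
#' @param coverage optional numeric coverage vector (one per contig);
#'   otherwise parsed via [contig_coverage()].
#' @param sidecar optional sidecar table passed to [contig_coverage()].
#' @return the filtered `DNAStringSet`.
#' @export
filter_contigs <- function(contigs, min_len = 1000, min_cov = 5,
                           coverage = NULL, sidecar = NULL) {
  if (length(contigs) == 0) return(contigs)
  cov <- coverage %||% contig_coverage(contigs, sidecar)
  assert_that(length(cov) == length(contigs),
              "coverage vector length must match number of contigs")
  keep <- Biostrings::width(contigs) >= min_len & cov >= min_cov
  contigs[keep]
}
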