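#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

abort <- function(..., class = "leucopan_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) abort(...)
  invisible(TRUE)
}

#' Random nucleotide sequence
#'
#' Draws bases i.i.d. uniform over A/C/G/T using the current RNG state.
#'
#' @param n sequence length in bp.
#' @return a single character string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' First whitespace-delimited token of FASTA/FASTQ headers
#' @param x character vector of headers (or an XStringSet).
#' @return character vector of record IDs.
#' @export
seq_ids <- function(x) {
  if (is(x, "XStringSet")) x <- names(x)
  sub("\\s.*$", "", x)
}

#' Description part of FASTA/FASTQ headers (text after the ID)
#' @param x character vector of headers (or an XStringSet).
#' @return character vector (empty string where no description).
#' @export
seq_desc <- function(x) {
  if (is(x, "XStringSet")) x <- names(x)
  ifelse(grepl("\\s", x), sub("^\\S+\\s+", "", x), "")
}

# Parse `key=value` tokens out of a header description.
header_field <- function(x, key) {
  m <- regmatches(x, regexpr(paste0(key, "=\\S+"), x))
  out <- rep(NA_character_, length(x))
  hit <- grepl(paste0(key, "="), x)
  out[hit] <- sub(paste0("^.*", key, "="), "", m)
  out
}

#' Integer Phred scores of a quality-scaled read set
#' @param x a `QualityScaledDNAStringSet`.
#' @return a list of integer vectors, one per read.
#' @export
phred_scores <- function(x) {
  assert_that(is(x, "QualityScaledXStringSet"),
              "phred_scores() needs a QualityScaledDNAStringSet")
  as.list(as(Biostrings::quality(x), "IntegerList"))
}

phred_to_string <- function(q) {
  intToUtf8(pmin(pmax(as.integer(q), 0L), 93L) + 33L)
}

string_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}
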