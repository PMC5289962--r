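#' Read sequence records from FASTA or FASTQ
#'
#' FASTA is read into a `DNAStringSet` or `AAStringSet` depending on
#' `alphabet`; FASTQ (always nucleotide) is read into a
#' `QualityScaledDNAStringSet` with Phred+33 qualities. Record names keep the
#' full header line; use [seq_ids()] / [seq_desc()] to split ID and
#' description. No quality-encoding autodetection is attempted: FASTQ input
#' must be Phred+33.
#'
#' @param path path to an uncompressed FASTA/FASTQ file.
#' @param format `"fasta"` or `"fastq"`; `"auto"` guesses from the file
#'   extension (`.fq`/`.fastq` vs anything else).
#' @param alphabet `"DNA"` or `"AA"` (FASTA only).
#' @return an `XStringSet`; for FASTQ a `QualityScaledDNAStringSet`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           alphabet = c("DNA", "AA")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  assert_that(file.exists(path), "no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (format == "fastq") {
    validate_fastq(path)
    # Biostrings warns about dropping its own internal metadata columns here
    return(withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
  }
  x <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                error = function(e) abort("malformed FASTA in ", path, ": ",
                                          conditionMessage(e)))
  assert_that(all(Biostrings::width(x) > 0L),
              "empty sequence record(s) in ", path, ": ",
              paste(seq_ids(x)[Biostrings::width(x) == 0L], collapse = ", "))
  if (alphabet == "AA") Biostrings::AAStringSet(x) else Biostrings::DNAStringSet(x)
}

# Cheap structural scan so that parse errors can name the offending line.
validate_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    abort("truncated FASTQ: ", path, " has ", n,
          " lines (not a multiple of 4) near line ", n)
  for (i in seq(1L, n, by = 4L)) {
    if (!startsWith(lines[i], "@"))
      abort("FASTQ parse error at line ", i, ": header must start with '@'")
    if (!startsWith(lines[i + 2L], "+"))
      abort("FASTQ parse error at line ", i + 2L,
            ": separator must start with '+'")
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L]))
      abort("FASTQ parse error at line ", i + 3L,
            ": quality length differs from sequence length")
    if (nchar(lines[i + 1L]) == 0L)
      abort("FASTQ parse error at line ", i + 1L, ": empty sequence")
  }
  invisible(TRUE)
}

#' Write sequence records to FASTA or FASTQ
#'
#' @param x an `XStringSet`; a `QualityScaledDNAStringSet` is required for
#'   FASTQ output.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"` (default taken from the object type).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = NULL) {
  if (is.null(format)) {
    format <- if (is(x, "QualityScaledXStringSet")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    assert_that(is(x, "QualityScaledXStringSet"),
                "FASTQ output needs per-base qualities")
    Biostrings::writeQualityScaledXStringSet(x, path)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}
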