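#' Default pipeline configuration
#'
#' One nested list holding every tunable parameter of the pipeline, grouped
#' by stage. All values have defaults; [write_config()] / [read_config()]
#' round-trip the structure losslessly through an INI-style text file.
#'
#' @return a named list of named lists (class `leucopan_config`).
#' @export
pipeline_config <- function() {
  structure(list(
    contigs = list(min_len = 1000, min_cov = 5),
    clustering = list(inflation = 1.5, min_identity = 0.30,
                      min_coverage = 0.75, gap_open = 11, gap_extend = 1,
                      kmer_len = 5, kmer_stride = 7, band_extra = 24,
                      max_mcl_iters = 200, convergence_tol = 1e-6,
                      singleton_curation_identity = 0.5,
                      singleton_length_deviation = 0.5,
                      singleton_hit_coverage = 0.3),
    pancore = list(n_orders = 1000, soft_core_fraction = 1.0),
    lineage = list(linkage = "complete", k_max = 20),
    screen = list(window_len = 500, flank_len = 25,
                  flank_min_consensus = 1.0, min_interspecies_diffs = 5,
                  max_offtarget_identity = 0.85, max_primer_mismatches = 2),
    quant = list(min_overlap = 20, max_overlap_mismatch_frac = 0.1,
                 max_expected_errors = 1.0, denoise_max_diffs = 1,
                 denoise_abundance_skew = 8, discard_singletons = FALSE,
                 min_classify_identity = 0.97)
  ), class = "leucopan_config")
}

#' Write a pipeline configuration to an INI-style file
#' @param cfg a config list as returned by [pipeline_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.logical(v)) as.character(v)
    else if (is.numeric(v)) format(v, digits = 17, scientific = TRUE, trim = TRUE)
    else as.character(v)
  }
  out <- character(0)
  for (sec in names(cfg)) {
    out <- c(out, paste0("[", sec, "]"))
    for (key in names(cfg[[sec]]))
      out <- c(out, paste0(key, " = ", fmt(cfg[[sec]][[key]])))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config()]
#' @param path path to the INI-style config file.
#' @return a `leucopan_config` list.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "no such config file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list(); sec <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- sub("^\\[(.*)\\]$", "\\1", ln)
      cfg[[sec]] <- list()
    } else {
      assert_that(!is.null(sec), "config entry before any [section]: ", ln)
      kv <- strsplit(ln, "\\s*=\\s*")[[1]]
      assert_that(length(kv) == 2L, "malformed config line: ", ln)
      val <- kv[2]
      parsed <- if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else if (grepl("^[0-9.eE+-]+$", val) &&
               !is.na(suppressWarnings(as.numeric(val)))) as.numeric(val)
      else val
      cfg[[sec]][[kv[1]]] <- parsed
    }
  }
  structure(cfg, class = "leucopan_config")
}
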