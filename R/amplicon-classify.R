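#' Classify centroids against a reference allele database
#'
#' Each centroid is globally aligned to every reference allele; identity is
#' matches over alignment columns. The top-hit species is assigned when its
#' identity reaches `min_classify_identity`; an exact identity tie between
#' alleles of different species yields `"ambiguous"` (counted as
#' unclassified downstream). An optional label-merge map collapses
#' reference labels that the marker cannot separate (e.g. genomically
#' inseparable species pairs) before tie evaluation.
#'
#' @param centroids a `unique_sequences` data.frame (see [denoise()]) or
#'   character vector of sequences.
#' @param reference allele `DNAStringSet` with `species=` header tags.
#' @param params a [quant_params()].
#' @param merge_map optional named character vector mapping reference
#'   species labels to merged output labels.
#' @return data.frame with `seq`, `abundance`, `species` (label,
#'   `"ambiguous"`, or `"unclassified"`) and `identity` of the best hit.
#' @export
classify <- function(centroids, reference, params = quant_params(),
                     merge_map = NULL) {
  assert_that(length(reference) > 0, "empty reference")
  ref_sp <- unname(allele_species(reference))
  if (!is.null(merge_map)) {
    hit <- ref_sp %in% names(merge_map)
    ref_sp[hit] <- merge_map[ref_sp[hit]]
  }
  seqs <- if (is.data.frame(centroids)) centroids$seq else
    as.character(centroids)
  ab <- if (is.data.frame(centroids)) centroids$abundance else
    rep(1, length(seqs))
  species <- character(length(seqs)); ident <- numeric(length(seqs))
  refs <- Biostrings::DNAStringSet(reference)
  ref_chr <- as.character(refs)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1,
                                                      baseOnly = FALSE)
  # Hamming fast path: for equal lengths (L - d) / L equals the
  # global-alignment identity whenever the optimal alignment is gap-free
  # (always the case near 100% identity) and is a lower bound otherwise.
  ham <- hamming_matrix(seqs, ref_chr)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    idents <- ifelse(ham[i, ] >= 0, (L - ham[i, ]) / L, NA_real_)
    if (anyNA(idents)) {
      mism <- which(is.na(idents))
      aln <- Biostrings::pairwiseAlignment(
        rep(Biostrings::DNAStringSet(seqs[i]), length(mism)), refs[mism],
        type = "global", substitutionMatrix = sub_mat,
        gapOpening = 4, gapExtension = 1)
      aln_len <- nchar(as.character(Biostrings::alignedPattern(aln)))
      idents[mism] <- Biostrings::nmatch(aln) / aln_len
    }
    best <- max(idents)
    ident[i] <- best
    if (best < params$min_classify_identity) {
      species[i] <- "unclassified"
    } else {
      top_sp <- unique(ref_sp[idents == best])
      species[i] <- if (length(top_sp) > 1) "ambiguous" else top_sp
    }
  }
  data.frame(seq = seqs, abundance = ab, species = species,
             identity = ident, stringsAsFactors = FALSE)
}

#' Species composition across replicates
#'
#' Per replicate, each species' fraction is its classified abundance share
#' of all centroid reads in that replicate; ambiguous and unclassified
#' abundance is pooled into an `unclassified` fraction, so the per-replicate
#' fractions sum to one. Means and standard deviations are taken over
#' replicates; a replicate with zero classified reads is flagged and
#' excluded from the mean with a warning.
#'
#' @param assignments list with one [classify()] result per replicate.
#' @return list of class `composition_table`: `per_replicate` (data.frame
#'   `replicate`, `species`, `fraction`), `summary` (`species`, `mean`,
#'   `sd`), and `excluded_replicates`.
#' @export
compose <- function(assignments) {
  assert_that(length(assignments) >= 1, "need at least one replicate")
  reps <- names(assignments) %||% sprintf("rep%d", seq_along(assignments))
  species_all <- sort(unique(unlist(lapply(assignments, function(a)
    setdiff(a$species, c("ambiguous", "unclassified"))))))
  rows <- list(); excluded <- character(0)
  for (r in seq_along(assignments)) {
    a <- assignments[[r]]
    total <- sum(a$abundance)
    classified <- a$species %in% species_all
    if (total == 0 || !any(classified)) {
      warning("replicate ", reps[r],
              " has no classified reads; excluded from the mean")
      excluded <- c(excluded, reps[r])
      next
    }
    fr <- vapply(species_all, function(s)
      sum(a$abundance[a$species == s]) / total, numeric(1))
    rows[[length(rows) + 1]] <- data.frame(
      replicate = reps[r],
      species = c(species_all, "unclassified"),
      fraction = c(fr, 1 - sum(fr)),
      stringsAsFactors = FALSE)
  }
  per_rep <- do.call(rbind, rows)
  spl <- split(per_rep$fraction, per_rep$species)
  summary <- data.frame(
    species = names(spl),
    mean = vapply(spl, mean, numeric(1)),
    sd = vapply(spl, function(x) if (length(x) > 1) sd(x) else 0,
                numeric(1)),
    row.names = NULL)
  summary <- summary[order(match(summary$species,
                                 c(species_all, "unclassified"))), ]
  rownames(summary) <- NULL
  structure(list(per_replicate = per_rep, summary = summary,
                 excluded_replicates = excluded),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Species composition over",
      length(unique(x$per_replicate$replicate)), "replicate(s):\n")
  print(transform(x$summary, mean = round(100 * mean, 2),
                  sd = round(100 * sd, 2)), row.names = FALSE)
  cat("(mean/sd in percent)\n")
  invisible(x)
}

#' Run the full amplicon quantification pipeline on replicate read pairs
#'
#' Chains [merge_pairs()], [quality_filter()], [dereplicate()], [denoise()]
#' and [classify()] per replicate, then [compose()]s the replicates. Read
#' counts are tracked at every stage so conservation can be audited.
#'
#' @param replicates list with one `list(r1 = , r2 = )` per replicate
#'   (`QualityScaledDNAStringSet`s), e.g. from [simulate_amplicon_reads()].
#' @param reference allele `DNAStringSet` with `species=` tags.
#' @param params a [quant_params()].
#' @param merge_map optional label-merge map (see [classify()]).
#' @return list of class `amplicon_quant`: `composition`
#'   (a `composition_table`), `stage_counts` (data.frame per replicate:
#'   input/merged/filtered/unique/centroid read counts), and the
#'   per-replicate `assignments`.
#' @export
quantify_amplicons <- function(replicates, reference,
                               params = quant_params(), merge_map = NULL) {
  assignments <- list(); counts <- list()
  for (r in seq_along(replicates)) {
    rep_r <- replicates[[r]]
    mg <- merge_pairs(rep_r$r1, rep_r$r2, params)
    fl <- quality_filter(mg, params)
    un <- dereplicate(fl)
    cn <- denoise(un, params)
    cl <- classify(cn, reference, params, merge_map)
    assignments[[r]] <- cl
    counts[[r]] <- data.frame(
      replicate = names(replicates)[r] %||% sprintf("rep%d", r),
      n_pairs = mg$n_input, n_merged = mg$n_merged,
      n_unmerged = mg$n_unmerged, n_filtered = fl$n_kept,
      n_qc_fail = fl$n_discarded, n_unique = nrow(un),
      n_unique_reads = sum(un$abundance), n_centroids = nrow(cn),
      n_centroid_reads = sum(cn$abundance),
      stringsAsFactors = FALSE)
  }
  names(assignments) <- vapply(counts, `[[`, character(1), "replicate")
  structure(list(composition = compose(assignments),
                 stage_counts = do.call(rbind, counts),
                 assignments = assignments),
            class = "amplicon_quant")
}
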