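test_that("center-star alignment preserves sequences and picks the best center", {
  same <- Biostrings::DNAStringSet(c(a = "ACGTACGT", b = "ACGTACGT",
                                     c = "ACGTACGT"))
  aln0 <- align_cluster(same)
  expect_false(any(grepl("-", unclass(aln0))))

  ins <- Biostrings::DNAStringSet(c(a = "ACGTTTACGT", b = "ACGTTTTACGT"))
  aln1 <- align_cluster(ins)
  m <- do.call(rbind, strsplit(unclass(aln1), ""))
  gap_cols <- which(apply(m, 2, function(col) any(col == "-")))
  expect_length(gap_cols, 1)

  # every row ungaps back to its input; the chosen center maximizes the
  # summed pairwise global-alignment score (independent recomputation)
  set.seed(6)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = TRUE)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    base <- strsplit(random_dna(60), "")[[1]]
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      pos <- sample(60, 6)
      s[pos] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
      if (runif(1) < 0.5) s <- append(s, "A", after = sample(59, 1))
      paste(s, collapse = "")
    }, character(1))
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- paste0("s", seq_len(n))
    aln <- align_cluster(x)
    expect_equal(gsub("-", "", unclass(aln)), as.character(x),
                 ignore_attr = TRUE)
    sums <- vapply(seq_len(n), function(i)
      sum(Biostrings::score(Biostrings::pairwiseAlignment(
        rep(x[i], n - 1), x[-i], type = "global",
        substitutionMatrix = submat, gapOpening = 0, gapExtension = 2))),
      numeric(1))
    expect_equal(attr(aln, "center"), names(x)[which.max(sums)])
  }
})

test_that("conservation profiles match brute-force column tallies", {
  aln <- structure(c(a = "AACA", b = "AACA", c = "ACCA", d = "AGG-"),
                   class = "center_star_msa")
  pr <- conservation_profile(aln)
  expect_equal(pr$consensus_frac[1], 1.0)
  expect_equal(pr$consensus_frac[2], 0.5)    # A,A,C,G -> modal 2/4
  expect_equal(pr$gap_frac[4], 0.25)

  set.seed(3)
  for (i in 1:50) {
    n <- sample(3:8, 1); L <- sample(10:30, 1)
    rows <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), L,
                                      replace = TRUE,
                                      prob = c(rep(0.22, 4), 0.12)),
                               collapse = ""))
    names(rows) <- paste0("s", seq_len(n))
    pr <- conservation_profile(structure(rows, class = "center_star_msa"))
    mat <- do.call(rbind, strsplit(rows, ""))
    for (j in sample(L, 3)) {
      col <- mat[, j]
      nong <- col[col != "-"]
      expect_equal(pr$gap_frac[j], mean(col == "-"))
      expect_equal(pr$consensus_frac[j],
                   if (length(nong) == 0) 0 else max(table(nong)) / n)
    }
  }
})

test_that("window scanning excludes conserved genes and rediscovers the planted marker", {
  # fully conserved gene: no inter-species variation -> excluded
  cons <- structure(setNames(rep(paste(rep("ACGTT", 120), collapse = ""), 4),
                             paste0("s", 1:4)),
                    class = "center_star_msa")
  prof <- conservation_profile(cons)
  groups <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  expect_equal(nrow(scan_candidate_windows(prof, cons, groups)), 0)

  for (seed in 1:3) {
    mm <- marker_model(seed = seed)
    al <- generate_marker_alleles(mm)
    aln <- align_cluster(al)
    pr <- conservation_profile(aln)
    cands <- scan_candidate_windows(pr, aln, allele_species(al),
                                    og_id = "marker")
    expect_equal(nrow(cands), 1)
    expect_equal(cands$win_start, 25)
    expect_equal(cands$win_end, 525)
    expect_gte(cands$discrimination, 2 * mm$min_interspecies_diffs)
    # discrimination equals the brute-force minimum inter-species Hamming
    # count inside the window
    chr <- as.character(al)
    sp <- allele_species(al)
    win <- substr(chr, 26, 525)
    pairs <- t(combn(seq_along(al), 2))
    pairs <- pairs[sp[pairs[, 1]] != sp[pairs[, 2]], , drop = FALSE]
    dmin <- min(apply(pairs, 1, function(p)
      sum(strsplit(win[p[1]], "")[[1]] != strsplit(win[p[2]], "")[[1]])))
    expect_equal(cands$discrimination, dmin)

    # invariance to input order
    perm <- sample(seq_along(al))
    aln2 <- align_cluster(al[perm])
    c2 <- scan_candidate_windows(conservation_profile(aln2), aln2,
                                 allele_species(al), og_id = "marker")
    expect_equal(c2$win_start, cands$win_start)
    expect_equal(c2$discrimination, cands$discrimination)
  }
})

test_that("off-target filtering mirrors the cross-reactivity exclusions", {
  mm <- small_marker_model(seed = 14)
  al <- generate_marker_alleles(mm)
  aln <- align_cluster(al)
  pr <- conservation_profile(aln)
  params <- screen_params(window_len = 120, flank_len = 25)
  cands <- scan_candidate_windows(pr, aln, allele_species(al), params,
                                  og_id = "eno_like")
  expect_gte(nrow(cands), 1)

  # off-target carrying both primer sites verbatim: removed
  set.seed(2)
  ot_hit <- Biostrings::DNAStringSet(c(
    bad = paste0(random_dna(40), cands$primer_fwd[1], random_dna(150),
                 revcomp_chr(cands$primer_rev[1]), random_dna(40))))
  kept <- offtarget_filter(cands[1, ], ot_hit, params)
  expect_equal(nrow(kept), 0)
  expect_match(attr(kept, "removed"), "both primers")

  # distant off-target: retained
  ot_far <- Biostrings::DNAStringSet(c(far = random_dna(400)))
  kept2 <- offtarget_filter(cands[1, ], ot_far, params)
  expect_equal(nrow(kept2), 1)

  # 16S-like scenario: only one candidate's primer sites occur in the
  # off-target; the eno-like candidate survives the same filter
  ssu_fwd <- random_dna(25); ssu_rev_site <- random_dna(25)
  ot_16s <- Biostrings::DNAStringSet(c(
    lactococcal = paste0(random_dna(30), ssu_fwd, random_dna(150),
                         ssu_rev_site, random_dna(30))))
  two <- rbind(transform(cands[1, ], og_id = "eno_like"),
               transform(cands[1, ],
                         og_id = "ssu_like",
                         primer_fwd = ssu_fwd,
                         primer_rev = revcomp_chr(ssu_rev_site),
                         window_consensus = random_dna(120)))
  kept3 <- offtarget_filter(two, ot_16s, params)
  expect_equal(kept3$og_id, "eno_like")
  expect_match(attr(kept3, "removed"), "ssu_like")
})

test_that("primer location reproduces the published eno amplicon geometry", {
  p <- eno_primers()
  set.seed(8)
  insert <- random_dna(300)
  tmpl <- paste0(p$forward, insert, revcomp_chr(p$reverse))
  hit <- locate_primers(tmpl, p)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, nchar(tmpl))
  expect_equal(hit$length, 300 + nchar(p$forward) + nchar(p$reverse))

  expect_null(locate_primers(random_dna(400), p))

  # mismatch tolerance boundary
  fwd_mut <- p$forward
  substr(fwd_mut, 10, 10) <- "A"           # one mismatch vs template
  tmpl2 <- paste0(fwd_mut, insert, revcomp_chr(p$reverse))
  expect_null(locate_primers(tmpl2, primer_pair(p$forward, p$reverse,
                                                max_mismatches = 0)))
  hit2 <- locate_primers(tmpl2, primer_pair(p$forward, p$reverse,
                                            max_mismatches = 1))
  expect_equal(hit2$start, 0L)

  # two disjoint amplicons force an explicit choice
  tmpl3 <- paste0(tmpl, random_dna(50), tmpl)
  expect_error(locate_primers(tmpl3, p), "non-overlapping")
})
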