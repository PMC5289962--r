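test_that("pair merging picks the best overlap and builds a quality-aware consensus", {
  set.seed(4)
  frag <- random_dna(100)
  r1 <- qreads(substr(frag, 1, 60), list(rep(30L, 60)))
  r2 <- qreads(revcomp_chr(substr(frag, 41, 100)), list(rep(30L, 60)))
  mg <- merge_pairs(r1, r2)
  expect_equal(mg$n_merged, 1)
  expect_equal(mg$stats$overlap, 20)
  expect_equal(mg$stats$mismatches, 0)
  expect_equal(unname(as.character(mg$reads)), frag)
  expect_equal(Biostrings::width(mg$reads), 100)

  # conflict: higher-quality base wins, consensus quality |q1 - q2|
  alt <- if (substr(frag, 50, 50) == "A") "C" else "A"
  a <- paste0(substr(frag, 1, 49), alt, substr(frag, 51, 60))
  mg2 <- merge_pairs(qreads(a, list(rep(30L, 60))),
                     qreads(revcomp_chr(substr(frag, 41, 100)),
                            list(rep(10L, 60))))
  expect_equal(mg2$stats$mismatches, 1)
  merged <- unname(as.character(mg2$reads))
  expect_equal(substr(merged, 50, 50), alt)      # Q30 beats Q10
  expect_equal(phred_scores(mg2$reads)[[1]][50], 20L)

  # overlap below the minimum: unmerged
  left <- qreads(paste0(random_dna(50), substr(frag, 1, 10)),
                 list(rep(30L, 60)))
  right <- qreads(revcomp_chr(paste0(substr(frag, 1, 10), random_dna(50))),
                  list(rep(30L, 60)))
  mg3 <- merge_pairs(left, right)
  expect_equal(mg3$n_unmerged, 1)
  expect_equal(mg3$n_input, mg3$n_merged + mg3$n_unmerged)
})

test_that("expected-error filtering follows the closed form and is monotone", {
  r_good <- qreads(random_dna(150), list(rep(40L, 150)))
  fl <- quality_filter(r_good)
  expect_equal(fl$expected_errors, 150 * 1e-4, tolerance = 1e-9)
  expect_equal(fl$n_kept, 1)

  r_bad <- qreads(random_dna(150), list(rep(2L, 150)))
  expect_equal(quality_filter(r_bad)$n_kept, 0)

  set.seed(10)
  reads <- qreads(replicate(30, random_dna(80)),
                  replicate(30, sample(2:41, 80, replace = TRUE),
                            simplify = FALSE))
  kept <- vapply(c(0.5, 1, 2, 5, 20),
                 function(th) quality_filter(
                   reads, quant_params(max_expected_errors = th))$n_kept,
                 numeric(1))
  expect_true(all(diff(kept) >= 0))
})

test_that("dereplication groups exact duplicates with deterministic ordering", {
  x <- c(rep("ACGT", 5), rep("TTTT", 2), "acgt")   # case-normalized
  un <- dereplicate(x)
  expect_equal(un$seq, c("ACGT", "TTTT"))
  expect_equal(un$abundance, c(6L, 2L))
  expect_equal(sum(un$abundance), length(x))
  expect_equal(lengths(un$member_read_ids), c(6L, 2L), ignore_attr = TRUE)

  tie <- dereplicate(c("GGGG", "AAAA"))
  expect_equal(tie$seq, c("AAAA", "GGGG"))         # lexicographic tie rule
})

test_that("denoising absorbs skewed near-variants and only those", {
  un <- structure(data.frame(
    seq = c("AAAAAAAAAA", "AAAAAAAAAC", "GGGGGGGGGG"),
    abundance = c(800L, 10L, 9L),
    stringsAsFactors = FALSE),
    class = c("unique_sequences", "data.frame"))
  dn <- denoise(un)
  expect_equal(dn$abundance[dn$seq == "AAAAAAAAAA"], 810)  # 800 >= 8 x 10
  expect_true("GGGGGGGGGG" %in% dn$seq)            # 3+ mismatches: centroid

  # abundance below the skew: not absorbed
  un2 <- structure(data.frame(seq = c("AAAAAAAAAA", "AAAAAAAAAC"),
                              abundance = c(50L, 10L),
                              stringsAsFactors = FALSE),
                   class = c("unique_sequences", "data.frame"))
  dn2 <- denoise(un2)
  expect_equal(nrow(dn2), 2)

  # read conservation through the stage
  expect_equal(sum(dn$abundance), sum(un$abundance))
})

test_that("denoising with singleton discard recovers exactly the true alleles", {
  al <- generate_marker_alleles(small_marker_model(seed = 3))
  truth <- sort(unique(as.character(al)))
  params <- quant_params(discard_singletons = TRUE, denoise_max_diffs = 2)
  for (seed in 1:10) {
    comm <- mock_community(
      proportions = c(spA = 0.4, spB = 0.35, spC = 0.25),
      n_read_pairs = 1500, read_len = 100, fragment_len = 170,
      error_rate = 0.01, replicates = 1, seed = seed)
    rr <- simulate_amplicon_reads(comm, al)[[1]]
    mg <- merge_pairs(rr$r1, rr$r2, params)
    fl <- quality_filter(mg, params)
    cn <- denoise(dereplicate(fl), params)
    expect_setequal(cn$seq, truth)
  }
})

test_that("classification assigns by identity with tie and threshold rules", {
  ref <- Biostrings::DNAStringSet(c(
    "a1 species=spA" = paste(rep("ACGTT", 20), collapse = ""),
    "b1 species=spB" = paste(rep("TGCAA", 20), collapse = "")))
  hit <- classify(as.character(ref[[1]]), ref)
  expect_equal(hit$species, "spA")
  expect_equal(hit$identity, 1.0)

  # below the identity gate: unclassified
  far <- paste(rep("ACGTT", 10), collapse = "")    # length mismatch, ~50%
  expect_equal(classify(far, ref)$species, "unclassified")

  # exact tie between species: ambiguous
  ref2 <- Biostrings::DNAStringSet(c(
    "a species=spA" = "AAAAAAAAAACCCCCCCCCC",
    "b species=spB" = "AAAAAAAAAAGGGGGGGGGG"))
  mid <- "AAAAAAAAAACCCCCGGGGG"
  expect_equal(classify(mid, ref2,
                        quant_params(min_classify_identity = 0.7))$species,
               "ambiguous")
  # a merge map collapses inseparable species before tie evaluation
  merged <- classify(mid, ref2, quant_params(min_classify_identity = 0.7),
                     merge_map = c(spA = "spAB", spB = "spAB"))
  expect_equal(merged$species, "spAB")
})

test_that("composition tables normalize, average and flag replicates correctly", {
  one <- list(data.frame(seq = "x", abundance = 50, species = "spA",
                         identity = 1))
  expect_equal(compose(one)$summary$mean[1], 1.0)

  tri <- data.frame(seq = c("x", "y", "z"),
                    abundance = c(60, 25, 15),
                    species = c("spA", "spB", "spC"), identity = 1)
  ct <- compose(list(r1 = tri))
  expect_equal(ct$per_replicate$fraction,
               c(0.60, 0.25, 0.15, 0))

  set.seed(19)
  reps <- lapply(1:3, function(i)
    data.frame(seq = letters[1:3],
               abundance = rpois(3, 200) + 1,
               species = c("spA", "spB", "unclassified"), identity = 1))
  ct3 <- compose(reps)
  # mean equals the arithmetic mean of per-replicate fractions
  for (sp in c("spA", "spB", "unclassified")) {
    per <- ct3$per_replicate$fraction[ct3$per_replicate$species == sp]
    expect_equal(ct3$summary$mean[ct3$summary$species == sp], mean(per))
  }
  # per-replicate fractions (species + unclassified) sum to one
  sums <- tapply(ct3$per_replicate$fraction, ct3$per_replicate$replicate,
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  none <- list(ok = tri,
               bad = data.frame(seq = "q", abundance = 5,
                                species = "unclassified", identity = 0.5))
  expect_warning(ct4 <- compose(none), "no classified reads")
  expect_equal(ct4$excluded_replicates, "bad")
})

test_that("the end-to-end amplicon pipeline conserves reads and is deterministic", {
  al <- generate_marker_alleles(small_marker_model(seed = 7))
  comm <- mock_community(proportions = c(spA = 0.6, spB = 0.4),
                         n_read_pairs = 600, read_len = 100,
                         fragment_len = 170, error_rate = 0.01,
                         replicates = 2, seed = 5)
  reads <- simulate_amplicon_reads(comm, al)
  q1 <- quantify_amplicons(reads, al)
  sc <- q1$stage_counts
  expect_true(all(sc$n_pairs == sc$n_merged + sc$n_unmerged))
  expect_true(all(sc$n_merged == sc$n_filtered + sc$n_qc_fail))
  expect_true(all(sc$n_unique_reads == sc$n_filtered))
  expect_true(all(sc$n_centroid_reads <= sc$n_unique_reads))

  q2 <- quantify_amplicons(reads, al)
  expect_identical(q1$composition$summary, q2$composition$summary)
})
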