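no_prefilter <- function(...) {
  clustering_params(kmer_stride = 1, min_shared_kmers = 1,
                    max_kmer_bucket = 10000, ...)
}

test_that("similarity edges honor identity, coverage and normalization contracts", {
  set.seed(101)
  s <- random_aa(200)
  prot <- list(G1 = Biostrings::AAStringSet(c(g1 = s)),
               G2 = Biostrings::AAStringSet(c(g2 = s)))
  e <- all_vs_all_similarity(prot, no_prefilter())
  expect_equal(nrow(e), 1)
  expect_equal(e$identity, 1.0)
  expect_equal(e$score, 1.0)
  expect_equal(e$coverage, 1.0)

  # 100 independent random pairs: no edge passes the default gates
  set.seed(202)
  n_edges <- 0
  for (i in 1:100) {
    p2 <- list(A = Biostrings::AAStringSet(structure(random_aa(200),
                                                     names = "a1")),
               B = Biostrings::AAStringSet(structure(random_aa(200),
                                                     names = "b1")))
    n_edges <- n_edges + nrow(all_vs_all_similarity(p2, no_prefilter()))
  }
  expect_equal(n_edges, 0)

  # truncated copy: coverage is measured on the shorter sequence
  half <- substr(s, 1, 100)
  p3 <- list(A = Biostrings::AAStringSet(c(full = s)),
             B = Biostrings::AAStringSet(c(frag = half)))
  e3 <- all_vs_all_similarity(p3, no_prefilter())
  expect_equal(nrow(e3), 1)
  expect_equal(e3$coverage, 1.0)
  expect_equal(e3$identity, 1.0)

  expect_error(all_vs_all_similarity(
    list(A = Biostrings::AAStringSet(), B = p3$B)), "empty proteome")
})

test_that("MCL keeps disconnected components apart and isolates singletons", {
  tri <- function(prefix) {
    g <- paste0(prefix, 1:3)
    do.call(rbind, lapply(1:2, function(i)
      do.call(rbind, lapply((i + 1):3, function(j)
        data.frame(gene_a = g[i], gene_b = g[j], score = 1,
                   stringsAsFactors = FALSE)))))
  }
  edges <- rbind(tri("a"), tri("b"))
  genes <- structure(rep(c("GA", "GB", "GC"), 2),
                     names = c(paste0("a", 1:3), paste0("b", 1:3)))
  ogs <- mcl_cluster(edges, genes)
  expect_equal(length(unique(ogs$og_id)), 2)
  expect_setequal(ogs$gene[ogs$og_id == ogs$og_id[ogs$gene == "a1"]],
                  paste0("a", 1:3))

  genes2 <- c(genes, structure("GD", names = "lonely"))
  ogs2 <- mcl_cluster(edges, genes2)
  expect_equal(length(unique(ogs2$og_id)), 3)
  expect_equal(sum(ogs2$gene == "lonely"), 1)
  # partition property: every gene in exactly one OG
  expect_setequal(ogs2$gene, names(genes2))
  expect_false(anyDuplicated(ogs2$gene) > 0)
})

test_that("MCL partitions match an independent reference implementation", {
  for (seed in 1:20) {
    g <- random_similarity_graph(sample(8:25, 1), seed = seed)
    nodes <- sort(unique(c(g$gene_a, g$gene_b)))
    genes <- structure(rep("G", length(nodes)), names = nodes)
    mine <- mcl_cluster(g, genes)
    ref <- reference_mcl(g, nodes, inflation = 1.5)
    expect_equal(partition_key(split(mine$gene, mine$og_id)),
                 partition_key(ref), info = paste("seed", seed))
  }
})

test_that("curation removes divergent fragment singletons but keeps novel genes", {
  # singleton with a high-identity best hit is retained
  ogs <- data.frame(og_id = c("OG1", "OG1", "OG2"),
                    genome = c("A", "B", "C"),
                    gene = c("x1", "x2", "y1"), stringsAsFactors = FALSE)
  edges <- data.frame(gene_a = c("x1", "x1"), gene_b = c("x2", "y1"),
                      score = c(1, 0.4), identity = c(1, 0.9),
                      coverage = c(1, 1), stringsAsFactors = FALSE)
  lens <- c(x1 = 100, x2 = 100, y1 = 40)
  cur <- curate_clusters(ogs, edges, lengths = lens)
  expect_true("y1" %in% cur$gene)      # identity 0.9 >= 0.5: keep

  # no-hit singleton is a novel gene, not a divergent fragment
  ogs2 <- rbind(ogs, data.frame(og_id = "OG3", genome = "D", gene = "z1"))
  lens2 <- c(lens, z1 = 33)
  cur2 <- curate_clusters(ogs2, edges, lengths = lens2)
  expect_true("z1" %in% cur2$gene)

  # low identity AND >50% length deviation: removed
  edges3 <- rbind(edges, data.frame(gene_a = "x1", gene_b = "w1",
                                    score = 0.1, identity = 0.35,
                                    coverage = 1))
  ogs3 <- rbind(ogs, data.frame(og_id = "OG4", genome = "E", gene = "w1"))
  lens3 <- c(lens, w1 = 40)
  cur3 <- curate_clusters(ogs3, edges3, lengths = lens3)
  expect_false("w1" %in% cur3$gene)
  expect_equal(attr(cur3, "removed"), "w1")
})

test_that("planted half-length diverged fragments are the exact curation casualties", {
  pop <- generate_pangenome_population(
    small_lineage_model(seed = 21, gene_length_range = c(300, 330)))
  prot <- pop$proteins
  # Inject 5 fragments, one per genome from five distinct families: each is
  # a sub-half-length copy keeping three intact 5-residue islands (aligned
  # with the k-mer sampling stride), joined by mild (-1) mismatches so the
  # local alignment always bridges them (identity ~0.45, below the 0.5
  # curation gate) and flanked by worst-scoring junk so it never extends
  # (coverage stays below the 0.75 edge gate). Such a gene gets no
  # clustering edge, lands as a singleton, but leaves a substantial
  # sub-threshold hit for the curator.
  B <- leucopan:::blosum62()
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mild <- function(b) {
    cand <- aa20[B[b, aa20] == -1]
    if (length(cand) == 0) cand <- aa20[which.min(abs(B[b, aa20] + 1))]
    cand[1]
  }
  harsh <- function(b) aa20[which.min(B[b, aa20])]
  frag_ids <- character(5)
  for (i in 1:5) {
    g <- names(prot)[i]
    src <- as.character(prot[[g]][[i]])
    half <- strsplit(substr(src, 1, floor(nchar(src) / 2) - 2), "")[[1]]
    islands <- c(15:19, 29:33, 43:47)
    bridges <- setdiff(20:42, islands)
    junk <- setdiff(seq_along(half), c(islands, bridges))
    half[bridges] <- vapply(half[bridges], mild, character(1))
    half[junk] <- vapply(half[junk], harsh, character(1))
    frag_ids[i] <- sprintf("%s_frag", g)
    frag <- Biostrings::AAStringSet(structure(paste(half, collapse = ""),
                                              names = frag_ids[i]))
    prot[[g]] <- c(prot[[g]], frag)
  }
  res <- cluster_proteomes(prot)
  expect_setequal(attr(res$ogs, "removed"), frag_ids)
  # the remaining genes cluster exactly as without the fragments
  expect_equal(ncol(res$pan), ncol(pop$truth$planted_presence))
})

test_that("pan-matrix collapses paralogs and recovers planted presence", {
  ogs <- data.frame(og_id = c("OG1", "OG1", "OG1", "OG2"),
                    genome = c("A", "A", "B", "A"),
                    gene = c("p1", "p2", "q1", "r1"),
                    stringsAsFactors = FALSE)
  pm <- build_pan_matrix(ogs)
  expect_equal(pm["A", "OG1"], 1L)     # 3 paralogs -> single 1
  expect_equal(pm["B", "OG2"], 0L)
  expect_equal(dim(pm), c(2L, 2L))

  pop <- generate_pangenome_population(small_lineage_model(seed = 4))
  res <- cluster_proteomes(pop$proteins)
  # OG membership equals planted families (ARI 1) ...
  fam <- pop$truth$family_of_gene
  og_of <- structure(res$ogs$og_id, names = res$ogs$gene)
  expect_equal(adjusted_rand_index(fam, og_of[names(fam)]), 1.0)
  # ... and the pan-matrix equals planted presence up to column order
  truth <- pop$truth$planted_presence
  key <- function(m) sort(unname(apply(m, 2, paste, collapse = "")))
  expect_equal(key(res$pan[rownames(truth), ]), key(truth))
})

test_that("genome input order permutes rows but not the column pattern multiset", {
  pop <- generate_pangenome_population(small_lineage_model(seed = 8))
  res1 <- cluster_proteomes(pop$proteins)
  perm <- rev(names(pop$proteins))
  res2 <- cluster_proteomes(pop$proteins[perm])
  key <- function(m, rows) sort(unname(apply(m[rows, ], 2, paste,
                                             collapse = "")))
  rows <- sort(rownames(res1$pan))
  expect_equal(key(res1$pan, rows), key(res2$pan, rows))
})
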