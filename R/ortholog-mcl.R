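#' Markov clustering of the similarity graph into ortholog groups
#'
#' Standard MCL on the weighted, undirected similarity graph: self-loops are
#' added with weight equal to the node's maximum incident edge weight,
#' columns are normalized to stochastic, and expansion (matrix square)
#' alternates with inflation (entrywise power, then renormalization) until
#' the largest entry change falls below `convergence_tol`. The converged
#' flow matrix is interpreted by assigning every node to its highest-flow
#' attractor (ties to the lexicographically first attractor); attractors
#' that retain flow on each other collapse into one cluster. Isolated genes
#' become singleton groups. Clustering runs independently per connected
#' component, which leaves the result unchanged and keeps the matrices
#' small.
#'
#' @param edges similarity edges from [all_vs_all_similarity()].
#' @param genes named character vector (gene ID -> genome ID) covering every
#'   gene, including genes with no edges; defaults to the gene table
#'   attached to `edges`.
#' @param params a [clustering_params()].
#' @return membership data.frame with columns `og_id`, `genome`, `gene`;
#'   OG IDs are assigned in order of each group's lexicographically smallest
#'   member.
#' @export
mcl_cluster <- function(edges, genes = NULL, params = clustering_params()) {
  if (is.null(genes)) {
    gt <- attr(edges, "genes")
    assert_that(!is.null(gt), "genes mapping required (gene -> genome)")
    genes <- structure(gt$genome, names = gt$gene)
  }
  unknown <- setdiff(unique(c(edges$gene_a, edges$gene_b)), names(genes))
  assert_that(length(unknown) == 0, "edges reference unknown gene(s): ",
              paste(head(unknown, 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "score")], directed = FALSE,
    vertices = data.frame(name = names(genes)))
  comp <- igraph::components(g)
  membership <- comp$membership[names(genes)]
  edge_comp <- unname(membership[edges$gene_a])
  edge_rows <- split(seq_len(nrow(edges)), edge_comp)
  clusters <- lapply(split(names(genes), membership), sort)
  multi <- which(lengths(clusters) > 1L)
  for (ci in multi) {
    members <- clusters[[ci]]           # sorted = lexicographic node order
    rows <- edge_rows[[as.character(ci)]]
    W <- matrix(0, length(members), length(members),
                dimnames = list(members, members))
    ia <- match(edges$gene_a[rows], members)
    ib <- match(edges$gene_b[rows], members)
    W[cbind(ia, ib)] <- edges$score[rows]
    W[cbind(ib, ia)] <- edges$score[rows]
    clusters[[ci]] <- mcl_flow_clusters(W, params)
  }
  clusters <- unlist(lapply(clusters, function(x)
    if (is.list(x)) x else list(x)), recursive = FALSE)
  firsts <- vapply(clusters, min, character(1))
  clusters <- clusters[order(firsts)]
  og_id <- sprintf("OG%05d", seq_along(clusters))
  out <- data.frame(
    og_id = rep(og_id, lengths(clusters)),
    gene = unlist(clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  out$genome <- unname(genes[out$gene])
  out <- out[, c("og_id", "genome", "gene")]
  rownames(out) <- NULL
  structure(out, curated = FALSE)
}

# MCL iteration on one dense weighted adjacency matrix (rownames = genes).
mcl_flow_clusters <- function(W, params) {
  diag(W) <- apply(W, 1, max)           # self-loop = max incident weight
  M <- sweep(W, 2, colSums(W), "/")
  for (it in seq_len(params$max_mcl_iters)) {
    M2 <- M %*% M
    M2 <- M2^params$inflation
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < params$convergence_tol) break
    if (it == params$max_mcl_iters)
      abort("MCL did not converge in ", params$max_mcl_iters,
            " iterations (residual ", format(delta, digits = 3), ")")
  }
  nodes <- rownames(M)
  attractors <- which(diag(M) > 1e-6)
  if (length(attractors) == 0) attractors <- seq_along(nodes)
  # merge attractors that retain flow on one another
  A <- (M[attractors, attractors, drop = FALSE] > 1e-6)
  A <- A | t(A); diag(A) <- TRUE
  sys_id <- igraph::components(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"))$membership
  # every node joins the system of its highest-flow attractor
  flows <- M[attractors, , drop = FALSE]
  best <- apply(flows, 2, which.max)    # ties -> first = lexicographic
  node_sys <- sys_id[best]
  unname(lapply(split(nodes, node_sys), sort))
}

#' Curate ortholog groups by removing divergent singleton fragments
#'
#' A singleton group is removed when its gene looks like an assembly or
#' annotation artifact: its best alignment identity to any other gene falls
#' below `singleton_curation_identity` AND its length deviates from that
#' best hit by more than `singleton_length_deviation` (fraction of the hit
#' length). The best hit is sought among the gated edges *and* the
#' sub-threshold search hits recorded by [all_vs_all_similarity()] (those
#' covering at least `singleton_hit_coverage` of the shorter sequence) —
#' a gene whose only relatives fall below the clustering thresholds is
#' exactly the divergent singleton this step targets. Singletons with no
#' hits at all are kept: they are novel genes, not divergent fragments.
#'
#' @param ogs membership data.frame from [mcl_cluster()].
#' @param edges similarity edges (with the `hits` attribute, when
#'   available, supplying sub-threshold alignments).
#' @param params a [clustering_params()].
#' @param lengths named integer vector of protein lengths; defaults to the
#'   gene table attached to `edges`.
#' @return the curated membership data.frame (attribute `curated = TRUE`);
#'   removed genes are recorded in attribute `removed`.
#' @export
curate_clusters <- function(ogs, edges, params = clustering_params(),
                            lengths = NULL) {
  if (is.null(lengths)) {
    gt <- attr(edges, "genes")
    assert_that(!is.null(gt), "lengths required (gene -> protein length)")
    lengths <- structure(gt$length, names = gt$gene)
  }
  counts <- table(ogs$og_id)
  singles <- names(counts)[counts == 1L]
  sub <- attr(edges, "hits")
  pool <- edges[, c("gene_a", "gene_b", "identity")]
  if (!is.null(sub) && nrow(sub) > 0)
    pool <- rbind(pool,
                  sub[sub$coverage >= params$singleton_hit_coverage,
                      c("gene_a", "gene_b", "identity")])
  drop_genes <- character(0)
  for (og in singles) {
    gene <- ogs$gene[ogs$og_id == og]
    hits <- pool[pool$gene_a == gene | pool$gene_b == gene, , drop = FALSE]
    if (nrow(hits) == 0) next
    best <- hits[which.max(hits$identity), ]
    other <- if (best$gene_a == gene) best$gene_b else best$gene_a
    len_dev <- abs(lengths[gene] - lengths[other]) / lengths[other]
    if (best$identity < params$singleton_curation_identity &&
        len_dev > params$singleton_length_deviation)
      drop_genes <- c(drop_genes, gene)
  }
  out <- ogs[!(ogs$gene %in% drop_genes), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curated") <- TRUE
  attr(out, "removed") <- drop_genes
  out
}

#' Build the binary genome x OG presence/absence pan-matrix
#'
#' Paralogs collapse to a single presence (cell is 1 iff the genome has at
#' least one member of the group); all-zero columns cannot arise from a
#' membership table and are dropped defensively.
#'
#' @param ogs membership data.frame (`og_id`, `genome`, `gene`).
#' @param genomes optional ordered genome IDs (rows); defaults to sorted
#'   unique genomes in `ogs`.
#' @return binary integer matrix, rows = genomes, columns = OG IDs.
#' @export
build_pan_matrix <- function(ogs, genomes = NULL) {
  genomes <- genomes %||% sort(unique(ogs$genome))
  og_ids <- sort(unique(ogs$og_id))
  pm <- matrix(0L, length(genomes), length(og_ids),
               dimnames = list(genomes, og_ids))
  pm[cbind(match(ogs$genome, genomes), match(ogs$og_id, og_ids))] <- 1L
  pm[, colSums(pm) > 0, drop = FALSE]
}

#' One-call ortholog clustering of a set of proteomes
#'
#' Convenience wrapper chaining [all_vs_all_similarity()], [mcl_cluster()],
#' [curate_clusters()] and [build_pan_matrix()].
#'
#' @inheritParams all_vs_all_similarity
#' @return list with `edges`, `ogs` (curated membership) and `pan` (the
#'   presence/absence matrix over all genomes, including genomes whose
#'   genes were all curated away).
#' @export
cluster_proteomes <- function(proteomes, params = clustering_params()) {
  edges <- all_vs_all_similarity(proteomes, params)
  ogs <- mcl_cluster(edges, params = params)
  ogs <- curate_clusters(ogs, edges, params)
  pan <- build_pan_matrix(ogs, genomes = names(proteomes))
  list(edges = edges, ogs = ogs, pan = pan)
}
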