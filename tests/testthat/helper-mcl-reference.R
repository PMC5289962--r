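# Independent reference implementation of Markov clustering, written against
# the textbook algorithm with explicit loops and a connected-component
# reading of the converged flow matrix. Used as the oracle for mcl_cluster().

reference_mcl <- function(edges, nodes, inflation = 1.5, tol = 1e-6,
                          max_iter = 300) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$gene_a[r], nodes); j <- match(edges$gene_b[r], nodes)
    W[i, j] <- edges$score[r]; W[j, i] <- edges$score[r]
  }
  for (i in seq_len(n)) {
    inc <- max(W[i, ])
    W[i, i] <- if (inc > 0) inc else 1
  }
  M <- W
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    for (j in seq_len(n)) E[, j] <- E[, j] / sum(E[, j])
    if (max(abs(E - M)) < tol) { M <- E; break }
    M <- E
  }
  A <- (M > 1e-6) | t(M > 1e-6)
  diag(A) <- TRUE
  # connected components by breadth-first search
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(A[v, ] & is.na(comp)))
    }
  }
  unname(lapply(split(nodes, comp), sort))
}

random_similarity_graph <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(n_nodes, 2))
  keep <- runif(nrow(pairs)) < 0.25
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(gene_a = nodes[pairs[, 1]], gene_b = nodes[pairs[, 2]],
             score = round(runif(nrow(pairs), 0.1, 1), 3),
             stringsAsFactors = FALSE)
}

partition_key <- function(clusters) {
  paste(sort(vapply(clusters, function(x) paste(sort(x), collapse = ","),
                    character(1))), collapse = ";")
}
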