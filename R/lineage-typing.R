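#' Manhattan distances between genomes on the pan-matrix
#'
#' `d(i, j) = sum_o |presence[i, o] - presence[j, o]|`; on a binary matrix
#' this counts the OGs present in exactly one of the two genomes.
#'
#' @param pm binary pan-matrix (genomes x OGs).
#' @return a `stats::dist` object labelled by genome ID.
#' @export
manhattan_distances <- function(pm) {
  assert_that(nrow(pm) >= 2, "need at least two genomes")
  dist(pm, method = "manhattan")
}

#' Agglomerative clustering of the genome distance matrix
#'
#' @param d a `dist` object (see [manhattan_distances()]).
#' @param linkage `"complete"` (default) or `"average"`.
#' @return an `hclust` dendrogram; merge heights are linkage distances.
#' @export
agglomerative_cluster <- function(d, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  assert_that(inherits(d, "dist"), "d must be a dist object")
  hclust(d, method = linkage)
}

#' Select the number of lineages with the L-method knee
#'
#' Builds the evaluation graph x = number of clusters (1..k_max), y = merge
#' height at which the dendrogram attains x clusters, then finds the knee:
#' for each candidate c two least-squares lines are fitted to the points
#' with `x <= c` and `x > c`, and c minimizing the length-weighted total
#' RMSE is returned. The candidate range is then iteratively shrunk toward
#' the current knee (to twice its position) until the choice is stable, as
#' in the original L-method.
#'
#' @param tree an `hclust` dendrogram with at least 4 leaves.
#' @param k_max largest cluster count considered; default
#'   `min(N - 1, 20)`.
#' @return the chosen cluster count k (k = 1 with a warning when the merge
#'   heights carry no structure).
#' @export
knee_select_k <- function(tree, k_max = NULL) {
  assert_that(inherits(tree, "hclust"), "tree must be an hclust object")
  N <- length(tree$order)
  assert_that(N >= 4, "need at least four leaves")
  k_max <- k_max %||% min(N - 1L, 20L)
  assert_that(k_max >= 2 && k_max <= N - 1, "k_max must lie in [2, N-1]")
  h <- sort(tree$height)
  # evaluation graph: y(x) = merge height that reduces x clusters to x - 1
  x <- 2:k_max
  y <- h[N - x + 1]
  if (max(y) - min(y) < .Machine$double.eps^0.5 * max(1, max(abs(y)))) {
    warning("all merge heights are equal; returning k = 1")
    return(1L)
  }
  cutoff_x <- k_max
  knee <- NA_integer_
  for (iter in 1:50) {
    use <- x <= cutoff_x
    new_knee <- lmethod_knee(x[use], y[use])
    if (identical(new_knee, knee)) break
    knee <- new_knee
    cutoff_x <- min(max(2L * knee, 6L), k_max)  # keep >= 5 points in range
  }
  knee
}

# Two-segment least-squares fit; returns the x value at the breakpoint
# minimizing the length-weighted total RMSE (ties -> smallest x).
lmethod_knee <- function(x, y) {
  n <- length(x)
  if (n < 4) return(x[which.max(abs(diff(y)))])
  best <- Inf; best_c <- x[2]
  for (ci in 2:(n - 2)) {
    left <- seq_len(ci); right <- (ci + 1):n
    rmse_l <- line_rmse(x[left], y[left])
    rmse_r <- line_rmse(x[right], y[right])
    total <- (length(left) * rmse_l + length(right) * rmse_r) / n
    if (total < best - 1e-12) { best <- total; best_c <- x[ci] }
  }
  as.integer(best_c)
}

line_rmse <- function(x, y) {
  if (length(x) < 2) return(0)
  fit <- lm.fit(cbind(1, x), y)
  sqrt(mean(fit$residuals^2))
}

#' Cut the dendrogram into k lineages
#'
#' Labels are stable: lineages are numbered L1, L2, ... by the
#' lexicographically smallest genome ID they contain.
#'
#' @param tree an `hclust` dendrogram.
#' @param k number of lineages (1..N).
#' @return list of class `lineage_assignment`: `k`, `labels` (named
#'   character, genome -> lineage), `cut_height`.
#' @export
assign_lineages <- function(tree, k) {
  N <- length(tree$order)
  assert_that(k >= 1 && k <= N, "k must lie in [1, N]")
  raw <- cutree(tree, k = k)
  if (length(unique(raw)) != k)
    warning("tied merge heights: cut yields ", length(unique(raw)),
            " clusters by merge order, not ", k)
  mins <- vapply(split(names(raw), raw), min, character(1))
  labels <- sprintf("L%d", match(as.character(raw), names(sort(mins))))
  names(labels) <- names(raw)
  h <- sort(tree$height)
  cut_height <- if (k == 1) Inf
  else if (k >= N) 0
  else (h[N - k] + h[N - k + 1]) / 2
  structure(list(k = length(unique(labels)), labels = labels,
                 cut_height = cut_height, tree = tree),
            class = "lineage_assignment")
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat("Lineage assignment: k =", x$k, "(cut height",
      format(x$cut_height, digits = 4), ")\n")
  print(table(x$labels))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones.
#'
#' @param a,b label vectors (named vectors are matched by name).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  assert_that(length(a) == length(b), "labelings must cover the same items")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Lineage trait table with presence-fraction rendering
#'
#' For every trait (a named set of OGs) and every lineage, the cell fraction
#' is the share of lineage members carrying at least one OG of the trait
#' set. Fractions render as `"+"` (all members), `"-"` (none), or
#' `"+(NN%)"` with NN the percentage truncated to an integer, so 2 of 3
#' members renders as `"+(66%)"`.
#'
#' @param pm binary pan-matrix.
#' @param assignment a [assign_lineages()] result (or named label vector).
#' @param trait_map named list: trait name -> character vector of OG IDs.
#' @return character matrix (traits x lineages) of rendered cells, with the
#'   numeric fractions attached as attribute `fractions`.
#' @export
lineage_trait_table <- function(pm, assignment, trait_map) {
  labels <- if (inherits(assignment, "lineage_assignment"))
    assignment$labels else assignment
  labels <- labels[rownames(pm)]
  unknown <- setdiff(unlist(trait_map), colnames(pm))
  assert_that(length(unknown) == 0, "trait OG(s) not in pan-matrix: ",
              paste(unknown, collapse = ", "))
  lineages <- sort(unique(labels))
  frac <- matrix(0, length(trait_map), length(lineages),
                 dimnames = list(names(trait_map), lineages))
  for (tr in names(trait_map)) {
    has <- rowSums(pm[, trait_map[[tr]], drop = FALSE]) > 0
    for (ln in lineages)
      frac[tr, ln] <- mean(has[labels == ln])
  }
  rendered <- matrix(render_trait_cell(frac), nrow(frac), ncol(frac),
                     dimnames = dimnames(frac))
  attr(rendered, "fractions") <- frac
  rendered
}

render_trait_cell <- function(f) {
  ifelse(f >= 1, "+",
         ifelse(f <= 0, "-", sprintf("+(%d%%)", floor(100 * f))))
}
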