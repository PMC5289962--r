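#' Export a dendrogram as a Newick string
#'
#' Converts an `hclust` merge structure into Newick with branch lengths equal
#' to merge-height differences, so leaves sit at height 0 and each internal
#' node at its merge height (ultrametric). A single leaf may be given as a
#' length-one character vector.
#'
#' @param tree an `hclust` object, or a single leaf label.
#' @param path optional file to write the string to.
#' @param digits significant digits for branch lengths.
#' @return the Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  if (is.character(tree) && length(tree) == 1L) {
    nwk <- paste0(tree, ";")
  } else {
    assert_that(inherits(tree, "hclust"), "tree must be an hclust object")
    labs <- tree$labels %||% as.character(seq_len(nrow(tree$merge) + 1L))
    assert_that(!anyDuplicated(labs), "duplicate leaf names: ",
                paste(unique(labs[duplicated(labs)]), collapse = ", "))
    fmt <- function(x) format(x, digits = digits, scientific = FALSE,
                              trim = TRUE)
    node_str <- function(i) {
      # i < 0: leaf -i at height 0; i > 0: merge row i at height[i]
      if (i < 0) list(str = labs[-i], h = 0)
      else {
        l <- node_str(tree$merge[i, 1]); r <- node_str(tree$merge[i, 2])
        h <- tree$height[i]
        list(str = paste0("(", l$str, ":", fmt(h - l$h), ",",
                          r$str, ":", fmt(h - r$h), ")"),
             h = h)
      }
    }
    nwk <- paste0(node_str(nrow(tree$merge))$str, ";")
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
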