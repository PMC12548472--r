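#' Patristic distances between the leaves of a tree
#'
#' The patristic distance between two leaves is the sum of branch lengths on
#' the path connecting them. Trees consumed here are read with
#' [read_newick()]; tree construction itself is out of scope.
#'
#' @param tree An [ape::phylo] object with branch lengths on every edge.
#' @return A [stats::dist] object labelled by the tip names.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' patristic_dist(tr)  # d(A,B) = 2, d(A,C) = d(B,C) = 4
#' @export
patristic_dist <- function(tree) {
  if (!inherits(tree, "phylo")) stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch length(s)", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch length(s)", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tree has duplicate leaf names", call. = FALSE)
  }
  as.dist(ape::cophenetic.phylo(tree))
}
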