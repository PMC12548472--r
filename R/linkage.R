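#' Complete-linkage agglomerative clustering
#'
#' Agglomerates the two clusters with the smallest complete-linkage
#' (maximum pairwise) distance at each step. Among equal merge candidates the
#' lexicographically smallest cluster-index pair (in order of cluster
#' creation) is taken, making the merge sequence fully deterministic. Merge
#' heights are nondecreasing.
#'
#' @param d A [stats::dist] object or symmetric nonnegative matrix with zero
#'   diagonal.
#' @return An object of class [stats::hclust] (usable with
#'   [stats::cutree()], `plot()`, etc.), with `method = "complete"`.
#' @export
hclust_complete <- function(d) {
  m <- as_dist_matrix(d)
  if (any(abs(diag(m)) > 1e-12)) stop("`d` must have a zero diagonal", call. = FALSE)
  n <- nrow(m)
  if (n < 2L) stop("need at least two items", call. = FALSE)
  labels <- rownames(m)

  # active clusters: list of member indices; id <0 => singleton, >0 => merge row
  members <- as.list(seq_len(n))
  ids <- -seq_len(n)
  D <- m
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(members)
    dd <- D
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    best <- which(dd == min(dd), arr.ind = TRUE)
    # lexicographically smallest (i, j) in cluster-creation order
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    height[step] <- D[i, j]
    merge[step, ] <- sort(c(ids[[i]], ids[[j]]))
    new_members <- c(members[[i]], members[[j]])
    # complete linkage: distance to the union is the max of the two
    if (k > 2L) {
      others <- setdiff(seq_len(k), c(i, j))
      newd <- pmax(D[i, others], D[j, others])
      D <- D[others, others, drop = FALSE]
      D <- rbind(cbind(D, newd), c(newd, 0))
      members <- c(members[others], list(new_members))
      ids <- c(ids[others], step)
    } else {
      members <- list(new_members)
      ids <- step
    }
  }
  # leaf order for plotting: recursive left-to-right traversal
  ord <- function(node) {
    if (node < 0L) return(-node)
    c(ord(merge[node, 1L]), ord(merge[node, 2L]))
  }
  structure(
    list(merge = merge, height = height, order = ord(n - 1L),
         labels = labels, method = "complete",
         call = match.call(), dist.method = NULL),
    class = "hclust"
  )
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges and returns the resulting partition,
#' with labels `"1"`, `"2"`, ... assigned in order of first appearance along
#' the original item ordering.
#'
#' @param hc An [stats::hclust] object (e.g. from [hclust_complete()]).
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Partition tibble with columns `item`, `label`.
#' @export
cut_k <- function(hc, k) {
  n <- length(hc$labels %||% hc$order)
  if (k < 1 || k > n) {
    stop(sprintf("`k` must be between 1 and %d", n), call. = FALSE)
  }
  cl <- cutree(hc, k = k)  # numbers clusters by first appearance already
  tibble::tibble(
    item = if (is.null(hc$labels)) as.character(seq_len(n)) else hc$labels,
    label = as.character(unname(cl))
  )
}
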