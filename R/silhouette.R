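#' Average silhouette coefficient of a partition
#'
#' For each item \eqn{i}, \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)} where
#' \eqn{a_i} is the mean distance to the other members of its own cluster
#' and \eqn{b_i} the smallest mean distance to another cluster. Items in
#' singleton clusters score 0 (standard convention), as does the degenerate
#' \eqn{a_i = b_i = 0} case. The partition-level score is the mean over all
#' items; values range from -1 (misassigned) to 1 (well separated).
#'
#' @param d A [stats::dist] object or symmetric matrix; labels must match
#'   the partition's items.
#' @param partition Partition data frame (item column + label column) with
#'   at least two distinct labels covering all items of `d`.
#' @return The average silhouette width (a single number).
#' @export
silhouette_avg <- function(d, partition) {
  m <- as_dist_matrix(d)
  p <- as_partition(partition)
  ids <- rownames(m)
  if (!setequal(ids, p$item)) {
    stop("partition items do not match the distance matrix labels", call. = FALSE)
  }
  lab <- p$label[match(ids, p$item)]
  if (length(unique(lab)) < 2L) {
    stop("silhouette needs at least two clusters", call. = FALSE)
  }
  n <- nrow(m)
  sizes <- table(lab)
  s <- vapply(seq_len(n), function(i) {
    own <- lab[i]
    if (sizes[[own]] == 1L) return(0)
    a <- sum(m[i, lab == own]) / (sizes[[own]] - 1L)
    b <- min(vapply(setdiff(names(sizes), own),
                    function(cl) mean(m[i, lab == cl]), numeric(1L)))
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1L))
  mean(s)
}

#' Silhouette sweep over the number of clusters
#'
#' Builds the complete-linkage dendrogram once, cuts it at each
#' `k = k_min, ..., k_max`, scores every cut with [silhouette_avg()], and
#' picks the `k` maximizing the average silhouette (ties resolved to the
#' smallest `k`).
#'
#' @param d A [stats::dist] object or symmetric matrix of dissimilarities.
#' @param k_min,k_max Sweep bounds; defaults 2 and `min(10, n - 1)`, with
#'   `2 <= k_min <= k_max <= n - 1`.
#' @return A `silhouette_sweep` tibble with columns `k` and
#'   `avg_silhouette`; attributes `chosen_k` and `hclust` carry the selected
#'   `k` and the dendrogram.
#' @seealso [cluster_phages()] for the one-call clustering chain.
#' @export
select_k <- function(d, k_min = 2, k_max = NULL) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  k_max <- k_max %||% min(10L, n - 1L)
  if (!(2 <= k_min && k_min <= k_max && k_max <= n - 1L)) {
    stop(sprintf("need 2 <= k_min <= k_max <= n - 1 (n = %d)", n), call. = FALSE)
  }
  hc <- hclust_complete(m)
  ks <- seq.int(k_min, k_max)
  avg <- vapply(ks, function(k) silhouette_avg(m, cut_k(hc, k)), numeric(1L))
  out <- tibble::tibble(k = as.integer(ks), avg_silhouette = avg)
  attr(out, "chosen_k") <- ks[which.max(avg)]  # first max -> smallest k
  attr(out, "hclust") <- hc
  class(out) <- c("silhouette_sweep", class(out))
  out
}

#' Cluster phages from a distance matrix, choosing k by silhouette
#'
#' The clustering chain used for mixed phenotype tables ([gower_dist()]) and
#' tree-derived distances ([patristic_dist()]) alike: complete-linkage
#' agglomeration, a silhouette sweep over candidate cluster numbers (unless
#' `k` is fixed), and a cut at the chosen `k`.
#'
#' @param d A [stats::dist] object or symmetric dissimilarity matrix.
#' @param k `"auto"` (default) to pick `k` by maximum average silhouette, or
#'   a fixed integer.
#' @param k_min,k_max Sweep bounds passed to [select_k()].
#' @return A `phage_clustering` object: list with elements `hclust`, `sweep`
#'   (`NULL` when `k` is fixed), `k`, `avg_silhouette`, and `partition`
#'   (tibble `item`, `label`). Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
cluster_phages <- function(d, k = "auto", k_min = 2, k_max = NULL) {
  m <- as_dist_matrix(d)
  if (identical(k, "auto")) {
    sweep <- select_k(m, k_min = k_min, k_max = k_max)
    hc <- attr(sweep, "hclust")
    k_use <- attr(sweep, "chosen_k")
  } else {
    sweep <- NULL
    hc <- hclust_complete(m)
    k_use <- as.integer(k)
  }
  part <- cut_k(hc, k_use)
  avg <- if (k_use >= 2L) silhouette_avg(m, part) else NA_real_
  structure(
    list(hclust = hc, sweep = sweep, k = k_use,
         avg_silhouette = avg, partition = part, n = nrow(m)),
    class = "phage_clustering"
  )
}

#' @export
print.phage_clustering <- function(x, ...) {
  cat(sprintf("Phage clustering: %d items, complete linkage, k = %d (avg silhouette %.3f)\n",
              x$n, x$k, x$avg_silhouette))
  sizes <- table(x$partition$label)
  cat("Cluster sizes:", paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}
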