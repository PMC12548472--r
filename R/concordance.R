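#' Contingency table between two partitions
#'
#' Cross-tabulates the labels of two partitions over the same item set:
#' cell \eqn{n_{ij}} counts items with label \eqn{i} in the first partition
#' and \eqn{j} in the second.
#'
#' @param p1,p2 Partition data frames (item column + label column) over
#'   identical item sets.
#' @return Tibble with columns `label_1`, `label_2`, `n` (nonzero cells
#'   only), with the full integer table in attribute `"table"`.
#' @export
contingency_table <- function(p1, p2) {
  a <- as_partition(p1, "p1")
  b <- as_partition(p2, "p2")
  only_a <- setdiff(a$item, b$item)
  only_b <- setdiff(b$item, a$item)
  if (length(only_a) || length(only_b)) {
    stop(sprintf("partitions cover different items; only in p1: {%s}; only in p2: {%s}",
                 paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")),
         call. = FALSE)
  }
  b <- b[match(a$item, b$item), ]
  tab <- table(factor(a$label, levels = unique(a$label)),
               factor(b$label, levels = unique(b$label)))
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("label_1", "label_2", "n")
  out <- dplyr::filter(out, .data$n > 0)
  attr(out, "table") <- unclass(tab)
  out
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same items:
#' \deqn{ARI = (Index - Expected) / (Max - Expected)}
#' with `Index` the number of item pairs co-clustered in both partitions
#' (\eqn{\sum_{ij} \binom{n_{ij}}{2}}), `Expected` its value under random
#' label permutation (\eqn{\sum_i \binom{a_i}{2} \sum_j \binom{b_j}{2} /
#' \binom{n}{2}}), and `Max` the average of the two partitions' own pair
#' counts. ARI is 1 for identical partitions, about 0 for chance agreement,
#' and can be negative. In the degenerate case `Max == Expected` (both
#' partitions all singletons or both a single cluster) the formula is 0/0;
#' the value is defined as 1 for identical partitions and 0 otherwise, with
#' a warning.
#'
#' @param p1,p2 Partition data frames over identical item sets, n >= 2.
#' @return The ARI (a single number in \[-1, 1\]).
#' @examples
#' p <- tibble::tibble(item = letters[1:4], label = c("x", "x", "y", "y"))
#' q <- tibble::tibble(item = letters[1:4], label = c("1", "2", "1", "2"))
#' adjusted_rand(p, q)  # -0.5
#' @export
adjusted_rand <- function(p1, p2) {
  ct <- contingency_table(p1, p2)
  tab <- attr(ct, "table")
  n <- sum(tab)
  if (n < 2) stop("ARI needs at least two items", call. = FALSE)
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (isTRUE(all.equal(max_index, expected))) {
    identical_parts <- sum(rowSums(tab > 0) == 1L) == nrow(tab) &&
      sum(colSums(tab > 0) == 1L) == ncol(tab) && nrow(tab) == ncol(tab)
    warning("degenerate partitions (Max == Expected); ARI defined as 1 if identical, else 0",
            call. = FALSE)
    return(if (identical_parts) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Pairwise ARI across several classification schemes
#'
#' Computes the Adjusted Rand Index for every unordered pair of named
#' partitions, reporting both raw and 2-decimal display values. Labels are
#' first canonicalized with [normalize_labels()] (a no-op for ARI, which is
#' invariant under relabeling; done so compared partitions print
#' consistently).
#'
#' @param partitions Named list of partition data frames over the same
#'   items (at least two).
#' @return A `concordance` tibble with columns `partition_1`, `partition_2`,
#'   `ari`, `ari_rounded`.
#' @export
compare_partitions <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 2L) {
    stop("`partitions` must be a named list of at least two partitions", call. = FALSE)
  }
  nms <- names(partitions)
  if (is.null(nms) || any(!nzchar(nms))) {
    stop("every partition must be named", call. = FALSE)
  }
  partitions <- lapply(partitions, function(p) normalize_labels(as_partition(p)))
  pairs <- combn(seq_along(partitions), 2L)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(col) {
    i <- pairs[1L, col]; j <- pairs[2L, col]
    ari <- adjusted_rand(partitions[[i]], partitions[[j]])
    tibble::tibble(partition_1 = nms[i], partition_2 = nms[j],
                   ari = ari, ari_rounded = round(ari, 2))
  })
  class(out) <- c("concordance", class(out))
  out
}

#' Canonical first-appearance relabeling of a partition
#'
#' Rewrites labels as `"1"`, `"2"`, ... in order of first appearance along
#' the item ordering. Purely cosmetic for concordance analysis: the ARI is
#' invariant under any relabeling of either partition.
#'
#' @param partition Partition data frame (item column + label column).
#' @return Partition tibble with columns `item`, `label`.
#' @export
normalize_labels <- function(partition) {
  p <- as_partition(partition)
  first <- unique(p$label)
  p$label <- as.character(match(p$label, first))
  p
}
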