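# ggplot2 views of the package's result objects

#' Plot a silhouette sweep
#'
#' Average silhouette width against the number of clusters, with the chosen
#' k highlighted.
#'
#' @param object A `silhouette_sweep` from [select_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silhouette_sweep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$avg_silhouette)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "number of clusters k", y = "average silhouette width") +
    ggplot2::theme_minimal()
}

#' Plot a greedy panel-selection trajectory
#'
#' Cumulative distinct infection patterns as strains are added, with
#' per-step gains as bars.
#'
#' @param object A `panel_selection` from [greedy_panel()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panel_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$gain), fill = "steelblue", alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$cumulative)) +
    ggplot2::scale_x_continuous(breaks = df$rank, labels = df$strain_id) +
    ggplot2::labs(x = "selected strain (rank order)",
                  y = "discriminatory patterns (bars: gain, line: cumulative)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a pairwise concordance table
#'
#' Heatmap of Adjusted Rand Index values between classification schemes.
#'
#' @param object A `concordance` from [compare_partitions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance <- function(object, ...) {
  df <- tidy(object)
  df2 <- dplyr::bind_rows(df, dplyr::rename(df, partition_1 = "partition_2",
                                            partition_2 = "partition_1"))
  ggplot2::ggplot(df2, ggplot2::aes(x = .data$partition_1, y = .data$partition_2,
                                    fill = .data$ari)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$ari)), colour = "white") +
    ggplot2::scale_fill_gradient(limits = c(-1, 1), low = "grey20", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "ARI") +
    ggplot2::theme_minimal()
}

#' Plot a clustered dendrogram
#'
#' Draws the complete-linkage dendrogram of a [cluster_phages()] result with
#' leaves coloured by cluster membership.
#'
#' @param object A `phage_clustering` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phage_clustering <- function(object, ...) {
  seg <- dendrogram_segments(object$hclust)
  leaves <- tibble::tibble(
    x = seq_along(object$hclust$order),
    item = object$hclust$labels[object$hclust$order]
  )
  leaves$cluster <- object$partition$label[match(leaves$item, object$partition$item)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(seg$y),
                                    label = .data$item, colour = .data$cluster),
                       angle = 90, hjust = 1, size = 3) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.25, 0.05))) +
    ggplot2::labs(x = NULL, y = "merge height", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

# segment coordinates of an hclust dendrogram (x = leaf display position)
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- setNames(seq_len(n), hc$order)  # display position of each leaf
  node_x <- numeric(n - 1L)
  node_y <- hc$height
  segs <- vector("list", n - 1L)
  pos <- function(id) if (id < 0L) c(leaf_x[[as.character(-id)]], 0) else c(node_x[id], node_y[id])
  for (i in seq_len(n - 1L)) {
    l <- pos(hc$merge[i, 1L]); r <- pos(hc$merge[i, 2L])
    node_x[i] <- (l[1L] + r[1L]) / 2
    h <- hc$height[i]
    segs[[i]] <- tibble::tibble(
      x = c(l[1L], r[1L], l[1L]), xend = c(l[1L], r[1L], r[1L]),
      y = c(l[2L], r[2L], h), yend = c(h, h, h)
    )
  }
  dplyr::bind_rows(segs)
}
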