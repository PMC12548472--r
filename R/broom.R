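# broom-style accessors for the package's result objects

#' Tidiers for phagepanel result objects
#'
#' `tidy()` returns the per-element detail of a result as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `panel_selection`, `phage_clustering`, `silhouette_sweep` or
#'   `concordance` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name phagepanel-tidiers
NULL

#' @rdname phagepanel-tidiers
#' @export
tidy.panel_selection <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rank", "strain_id", "gain", "cumulative")])
}

#' @rdname phagepanel-tidiers
#' @export
glance.panel_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = nrow(x),
    total_patterns = if (nrow(x)) x$cumulative[nrow(x)] else 1L,
    saturation = attr(x, "saturation"),
    n_phages = attr(x, "n_phages"),
    n_strains = attr(x, "n_strains")
  )
}

#' @rdname phagepanel-tidiers
#' @export
tidy.phage_clustering <- function(x, ...) {
  x$partition
}

#' @rdname phagepanel-tidiers
#' @export
glance.phage_clustering <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, avg_silhouette = x$avg_silhouette)
}

#' @rdname phagepanel-tidiers
#' @export
tidy.silhouette_sweep <- function(x, ...) {
  tibble::tibble(k = x$k, avg_silhouette = x$avg_silhouette,
                 chosen = x$k == attr(x, "chosen_k"))
}

#' @rdname phagepanel-tidiers
#' @export
glance.silhouette_sweep <- function(x, ...) {
  k <- attr(x, "chosen_k")
  tibble::tibble(chosen_k = k,
                 max_avg_silhouette = x$avg_silhouette[x$k == k])
}

#' @rdname phagepanel-tidiers
#' @export
tidy.concordance <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("partition_1", "partition_2", "ari", "ari_rounded")])
}

#' @rdname phagepanel-tidiers
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), min_ari = min(x$ari), max_ari = max(x$ari))
}
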