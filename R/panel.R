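#' Count distinct infection patterns under a strain subset
#'
#' The discriminatory power of a set of host strains is the number of
#' distinct phage infection-pattern vectors once the infection matrix is
#' restricted to those strains. The empty subset leaves all phages
#' indistinguishable (one pattern).
#'
#' @param infections Infection matrix tibble (`phage_id` + 0/1 strain
#'   columns), e.g. from [read_infection_matrix()].
#' @param strains Character vector of strain ids (columns) to keep.
#' @return Integer: number of distinct restricted rows.
#' @export
pattern_count <- function(infections, strains) {
  infections <- validate_infection_matrix(infections)
  unknown <- setdiff(strains, names(infections)[-1L])
  if (length(unknown)) {
    stop(sprintf("unknown strain(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (length(strains) == 0L) return(1L)
  m <- as.matrix(infections[, strains, drop = FALSE])
  length(unique(apply(m, 1L, paste, collapse = "")))
}

#' Greedy selection of a discriminatory host panel
#'
#' Iteratively picks the strain whose addition most increases the number of
#' distinct phage infection patterns ([pattern_count()]) over the strains
#' already selected. Ties are broken by input column order. Selection stops
#' when no remaining strain adds a new pattern (saturation) or after
#' `max_strains` picks.
#'
#' @param infections Infection matrix tibble (`phage_id` + 0/1 strain
#'   columns).
#' @param max_strains Optional cap on panel size (positive integer).
#' @return A `panel_selection` tibble with one row per selected strain:
#'   `rank`, `strain_id`, `gain` (additional discriminatory patterns) and
#'   `cumulative` (cumulative discriminatory patterns). Attributes record
#'   the matrix dimensions and the saturation pattern count.
#' @examples
#' m <- tibble::tibble(phage_id = paste0("p", 1:4),
#'                     s1 = c(1, 0, 0, 0), s2 = c(0, 1, 0, 0),
#'                     s3 = c(0, 0, 1, 0), s4 = c(0, 0, 0, 1))
#' greedy_panel(m)
#' @export
greedy_panel <- function(infections, max_strains = NULL) {
  infections <- validate_infection_matrix(infections)
  if (nrow(infections) == 0L) stop("infection matrix has no phages", call. = FALSE)
  if (!is.null(max_strains) && max_strains < 1) {
    stop("`max_strains` must be at least 1", call. = FALSE)
  }
  all_strains <- names(infections)[-1L]
  m <- as.matrix(infections[-1L])
  rownames(m) <- infections$phage_id

  selected <- character(0)
  keys <- rep("", nrow(m))  # running restricted-pattern key per phage
  current <- 1L
  steps <- list()
  limit <- min(length(all_strains), max_strains %||% length(all_strains))
  while (length(selected) < limit) {
    remaining <- setdiff(all_strains, selected)
    counts <- vapply(remaining, function(s) {
      length(unique(paste(keys, m[, s])))
    }, integer(1L))
    best <- remaining[which.max(counts)]  # first max = input column order
    gain <- max(counts) - current
    if (gain <= 0L) break
    selected <- c(selected, best)
    keys <- paste(keys, m[, best])
    current <- current + gain
    steps[[length(steps) + 1L]] <- tibble::tibble(
      rank = length(selected), strain_id = best,
      gain = gain, cumulative = current
    )
  }
  out <- if (length(steps)) dplyr::bind_rows(steps) else {
    tibble::tibble(rank = integer(), strain_id = character(),
                   gain = integer(), cumulative = integer())
  }
  attr(out, "n_phages") <- nrow(m)
  attr(out, "n_strains") <- length(all_strains)
  attr(out, "saturation") <- pattern_count(infections, all_strains)
  class(out) <- c("panel_selection", class(out))
  out
}
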