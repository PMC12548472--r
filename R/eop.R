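#' Efficiency of plating (EoP) from spot-test titers
#'
#' EoP is the ratio of a phage's plaque-forming titer on a test strain to its
#' titer on the reference (wild-type) strain; `log_eop` is its base-10
#' logarithm. A test titer of `NA` (ND, "not detected": no plaques at any
#' dilution) or 0 is complete loss of infectivity: EoP 0, `log_eop = -Inf`.
#'
#' @param titer_test Numeric vector of test-strain titers; `NA` = ND.
#' @param titer_reference Positive reference-strain titer(s); ND is not
#'   allowed (the reference must be countable).
#' @return A tibble with columns `eop` and `log_eop`, one row per input.
#' @examples
#' compute_eop(c(1e7, 1e5, NA), 1e7)
#' @export
compute_eop <- function(titer_test, titer_reference) {
  if (anyNA(titer_reference) || any(titer_reference <= 0)) {
    stop("`titer_reference` must be a positive count (the reference strain must be countable)",
         call. = FALSE)
  }
  if (any(titer_test < 0, na.rm = TRUE)) {
    stop("`titer_test` must be nonnegative or NA (ND)", call. = FALSE)
  }
  eop <- ifelse(is.na(titer_test), 0, titer_test / titer_reference)
  log_eop <- ifelse(eop == 0, -Inf, log10(eop))
  tibble::tibble(eop = eop, log_eop = log_eop)
}

#' Aggregate replicate log-EoP values
#'
#' ND replicates (`-Inf`) are dropped and the arithmetic mean of the
#' remaining finite log-EoP values is returned, together with how many
#' replicates were used and how many NDs were discarded. If every replicate
#' is ND the summary is `-Inf`.
#'
#' @param log_eop Nonempty numeric vector of per-replicate log-EoP values;
#'   `-Inf` marks an ND replicate.
#' @return One-row tibble with `log_eop`, `n_replicates_used`, `n_nd_dropped`.
#' @examples
#' aggregate_log_eop(c(-1.5, -2, -2.5, -Inf, -Inf, -Inf, -Inf))
#' @export
aggregate_log_eop <- function(log_eop) {
  if (length(log_eop) == 0L) stop("no replicates to aggregate", call. = FALSE)
  if (anyNA(log_eop)) stop("log_eop replicates must not be NA; encode ND as -Inf", call. = FALSE)
  finite <- log_eop[is.finite(log_eop)]
  n_total <- length(log_eop)
  tibble::tibble(
    log_eop = if (length(finite)) mean(finite) else -Inf,
    n_replicates_used = length(finite),
    n_nd_dropped = n_total - length(finite)
  )
}

#' Call a reduction in infection efficiency
#'
#' A phage-strain pair is called "reduced" when plating efficiency drops more
#' than 10-fold relative to the wild type, i.e. `log_eop < -1` strictly; a
#' boundary value of exactly -1 is not a reduction, and ND (`-Inf`) always is.
#'
#' @param log_eop Numeric vector of (aggregated) log-EoP values.
#' @return Logical vector.
#' @export
call_reduction <- function(log_eop) {
  log_eop < -1
}

#' Adsorption assay: rate and receptor-mutant call
#'
#' The unadsorbed ratio is the plaque count 10 minutes after phage addition
#' divided by the count at time zero; the adsorption rate is
#' `100 * (1 - unadsorbed)` percent. Strains with a rate strictly below 20%
#' are designated target-receptor mutants.
#'
#' @param plaques_t0 Positive plaque count(s) at 0 min.
#' @param plaques_t10 Nonnegative plaque count(s) at 10 min.
#' @return Tibble with `adsorption_rate` (percent) and `is_receptor_mutant`.
#' @examples
#' adsorption_rate(100, 81)  # 19% -> receptor mutant
#' @export
adsorption_rate <- function(plaques_t0, plaques_t10) {
  if (any(is.na(plaques_t0)) || any(plaques_t0 <= 0)) {
    stop("`plaques_t0` must be positive", call. = FALSE)
  }
  if (any(is.na(plaques_t10)) || any(plaques_t10 < 0)) {
    stop("`plaques_t10` must be nonnegative", call. = FALSE)
  }
  unadsorbed <- plaques_t10 / plaques_t0
  rate <- 100 * (1 - unadsorbed)
  tibble::tibble(adsorption_rate = rate, is_receptor_mutant = rate < 20)
}

#' Per-pair EoP records from a long titer table
#'
#' For every (phage, strain) pair, each replicate's titer is divided by the
#' matching replicate's titer on the reference strain, log-EoP values are
#' aggregated with [aggregate_log_eop()] (NDs dropped from the mean; all-ND
#' stays ND), and the >10-fold reduction call is made with
#' [call_reduction()].
#'
#' @param titers Tibble of titer observations with columns `phage_id`,
#'   `strain_id`, `replicate`, `titer` (`NA` = ND), as returned by
#'   [read_titer_table()].
#' @param reference_strain Identifier of the wild-type reference strain;
#'   its titers must be present, positive and never ND.
#' @return Tibble with one row per (phage, strain) pair: `eop`, `log_eop`,
#'   `reduced`, `n_replicates_used`, `n_nd_dropped`. The reference strain
#'   itself is excluded. `eop` is `10^log_eop` of the aggregated value
#'   (0 when ND).
#' @export
eop_table <- function(titers, reference_strain) {
  need <- c("phage_id", "strain_id", "replicate", "titer")
  missing_cols <- setdiff(need, names(titers))
  if (length(missing_cols)) {
    stop(sprintf("`titers` is missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  ref <- dplyr::filter(titers, .data$strain_id == reference_strain)
  if (nrow(ref) == 0L) {
    stop(sprintf("reference strain '%s' not found in `titers`", reference_strain),
         call. = FALSE)
  }
  if (anyNA(ref$titer) || any(ref$titer <= 0)) {
    stop(sprintf("reference strain '%s' has ND or non-positive titers; the reference must be countable",
                 reference_strain), call. = FALSE)
  }
  test <- dplyr::filter(titers, .data$strain_id != reference_strain)
  joined <- dplyr::inner_join(
    test,
    dplyr::select(ref, "phage_id", "replicate", ref_titer = "titer"),
    by = c("phage_id", "replicate")
  )
  dropped <- dplyr::anti_join(test, joined, by = c("phage_id", "strain_id", "replicate"))
  if (nrow(dropped) > 0L) {
    stop(sprintf("no reference titer for %d observation(s), e.g. phage '%s' replicate %d",
                 nrow(dropped), dropped$phage_id[1L], dropped$replicate[1L]),
         call. = FALSE)
  }
  per_rep <- dplyr::bind_cols(
    dplyr::select(joined, "phage_id", "strain_id"),
    compute_eop(joined$titer, joined$ref_titer)
  )
  out <- per_rep |>
    dplyr::group_by(.data$phage_id, .data$strain_id) |>
    dplyr::reframe(aggregate_log_eop(.data$log_eop)) |>
    dplyr::mutate(
      eop = ifelse(is.finite(.data$log_eop), 10^.data$log_eop, 0),
      reduced = call_reduction(.data$log_eop)
    ) |>
    dplyr::select("phage_id", "strain_id", "eop", "log_eop", "reduced",
                  "n_replicates_used", "n_nd_dropped")
  # preserve input ordering of phages and strains
  out[order(match(out$phage_id, unique(test$phage_id)),
            match(out$strain_id, unique(test$strain_id))), ]
}
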