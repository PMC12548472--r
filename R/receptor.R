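#' Derive receptor-requirement profiles from reduction calls
#'
#' Infers, for every phage, which host genes its infection requires, from
#' loss-of-infectivity calls on resistant mutant strains whose mutated genes
#' are known. The logic mirrors how receptor genes are read off a
#' resistant-mutant screen:
#'
#' * a phage's candidate genes are the union of the mutated-gene sets of the
#'   strains that block it (reduction call `TRUE`);
#' * *exoneration*: if a strain whose mutated genes are a subset of some
#'   blocking strain's genes does **not** block the phage, those genes are
#'   removed from the candidates (the classic case is a single-gene mutant
#'   shared with a double mutant: the phage still infecting the single mutant
#'   clears that gene);
#' * surviving candidates that no blocking strain pins down to a single gene
#'   (after exoneration) are kept as required but flagged *ambiguous* -
#'   typically genes seen only in multi-gene mutants whose gene sets are not
#'   separable by any subset relation;
#' * `overrides` (external evidence such as single-gene knockout libraries or
#'   complementation) are applied last and clear the ambiguity flag.
#'
#' @param reduction Tibble with columns `phage_id`, `strain_id`, `reduced`
#'   (logical), e.g. the output of [eop_table()].
#' @param mutant_genes Tibble mapping `strain_id` to `gene_id`, one row per
#'   mutated gene; every strain in `reduction` must appear.
#' @param overrides Optional tibble with columns `phage_id`, `gene_id`,
#'   `value` (0/1) applied after inference.
#' @return A `receptor_profile` tibble: one row per (phage, gene) with
#'   `required` (0/1 integer) and `ambiguous` (logical), covering all phages
#'   and all genes of `mutant_genes`, in input order. Use
#'   [profile_matrix()] for the wide phage-by-gene view.
#' @seealso [assign_receptor_types()]
#' @export
derive_receptor_profile <- function(reduction, mutant_genes, overrides = NULL) {
  need <- c("phage_id", "strain_id", "reduced")
  missing_cols <- setdiff(need, names(reduction))
  if (length(missing_cols)) {
    stop(sprintf("`reduction` is missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (!all(c("strain_id", "gene_id") %in% names(mutant_genes))) {
    stop("`mutant_genes` needs columns strain_id and gene_id", call. = FALSE)
  }
  unknown <- setdiff(unique(reduction$strain_id), unique(mutant_genes$strain_id))
  if (length(unknown)) {
    stop(sprintf("strain(s) missing from the mutant-gene map: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  phages <- unique(reduction$phage_id)
  genes <- unique(mutant_genes$gene_id)
  gene_sets <- split(mutant_genes$gene_id, mutant_genes$strain_id)

  rows <- purrr::map(phages, function(p) {
    sub <- reduction[reduction$phage_id == p, ]
    blocking <- unique(sub$strain_id[sub$reduced])
    nonblocking <- unique(sub$strain_id[!sub$reduced])
    b_sets <- gene_sets[blocking]
    candidates <- unique(unlist(b_sets, use.names = FALSE))
    exonerated <- character(0)
    for (s in nonblocking) {
      gs <- gene_sets[[s]]
      if (any(vapply(b_sets, function(b) all(gs %in% b), logical(1L)))) {
        exonerated <- union(exonerated, gs)
      }
    }
    required_genes <- setdiff(candidates, exonerated)
    # a required gene is resolved if some blocking strain's post-exoneration
    # gene set is exactly that gene
    effective <- lapply(b_sets, function(b) setdiff(b, exonerated))
    resolved <- unlist(effective[vapply(effective, length, integer(1L)) == 1L],
                       use.names = FALSE)
    tibble::tibble(
      phage_id = p,
      gene_id = genes,
      required = as.integer(genes %in% required_genes),
      ambiguous = genes %in% setdiff(required_genes, resolved)
    )
  })
  out <- dplyr::bind_rows(rows)

  if (!is.null(overrides)) {
    if (!all(c("phage_id", "gene_id", "value") %in% names(overrides))) {
      stop("`overrides` needs columns phage_id, gene_id, value", call. = FALSE)
    }
    if (!all(overrides$value %in% c(0, 1))) {
      stop("override values must be 0 or 1", call. = FALSE)
    }
    for (i in seq_len(nrow(overrides))) {
      hit <- out$phage_id == overrides$phage_id[i] & out$gene_id == overrides$gene_id[i]
      if (!any(hit)) {
        stop(sprintf("override targets unknown (phage, gene): ('%s', '%s')",
                     overrides$phage_id[i], overrides$gene_id[i]), call. = FALSE)
      }
      out$required[hit] <- as.integer(overrides$value[i])
      out$ambiguous[hit] <- FALSE
    }
  }
  class(out) <- c("receptor_profile", class(out))
  out
}

#' Wide phage-by-gene view of a receptor profile
#'
#' @param profile A `receptor_profile` tibble (long form), or any tibble with
#'   `phage_id`, `gene_id`, `required`.
#' @return Tibble with `phage_id` plus one 0/1 column per gene.
#' @export
profile_matrix <- function(profile) {
  tidyr::pivot_wider(
    dplyr::select(tibble::as_tibble(profile), "phage_id", "gene_id", "required"),
    names_from = "gene_id", values_from = "required"
  )
}

#' Assign lettered receptor types
#'
#' Phages with identical receptor-requirement rows (ambiguity flags ignored)
#' share a type; labels are consecutive letters `a`, `b`, `c`, ... in order
#' of first appearance along the phage ordering.
#'
#' @param profile A `receptor_profile` (long form from
#'   [derive_receptor_profile()]) or a wide phage-by-gene 0/1 tibble whose
#'   first column is `phage_id`.
#' @param phages Optional ordered subset of phage ids to type (defaults to
#'   all, in profile order).
#' @return Tibble with columns `phage_id`, `type`.
#' @examples
#' prof <- tibble::tibble(phage_id = c("p1", "p2", "p3"),
#'                        gA = c(1, 1, 0), gB = c(0, 0, 1))
#' assign_receptor_types(prof)
#' @export
assign_receptor_types <- function(profile, phages = NULL) {
  wide <- if (all(c("phage_id", "gene_id", "required") %in% names(profile))) {
    profile_matrix(profile)
  } else {
    tibble::as_tibble(profile)
  }
  if (names(wide)[1L] != "phage_id") names(wide)[1L] <- "phage_id"
  if (!is.null(phages)) {
    unknown <- setdiff(phages, wide$phage_id)
    if (length(unknown)) {
      stop(sprintf("unknown phage id(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    wide <- wide[match(phages, wide$phage_id), ]
  }
  key <- apply(as.matrix(wide[-1L]), 1L, paste, collapse = "\r")
  first <- !duplicated(key)
  labels <- setNames(type_letters(sum(first)), key[first])
  tibble::tibble(phage_id = wide$phage_id, type = unname(labels[key]))
}
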