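#' Published receptor-requirement matrix of the Wec phage collection
#'
#' The phage-by-gene requirement matrix of a 13-phage *Escherichia coli*
#' phage collection (ids `Wec172` ... `Wec196`) plus three validation phages
#' (`Wec270`, `Wec272`, and the FhuA-targeting reference phage `T5`,
#' untouched by any of the panel's mutations and hence an all-zero row).
#' Eight host genes are scored: the LPS biosynthesis genes *waaV*, *waaW*,
#' *waaY*, *waaT* and the membrane/flagellar genes *fihD*, *yhaH*, *nfrB*,
#' *tolA*. A 1 means the phage requires the gene product to infect.
#' Rows are in the published order; [assign_receptor_types()] on this matrix
#' reproduces the published lettered types (a-f for the originals, g for
#' T5).
#'
#' @param include_validation Include the three validation phages
#'   (default `TRUE`); `FALSE` restricts to the 13 original phages.
#' @return Tibble with `phage_id` plus eight 0/1 gene columns.
#' @export
wec_receptor_matrix <- function(include_validation = TRUE) {
  m <- tibble::tribble(
    ~phage_id, ~waaV, ~waaW, ~waaY, ~waaT, ~fihD, ~yhaH, ~nfrB, ~tolA,
    "Wec172",  1, 1, 0, 0, 0, 0, 0, 0,
    "Wec174",  1, 1, 1, 0, 0, 0, 0, 0,
    "Wec177",  1, 1, 1, 0, 0, 0, 0, 0,
    "Wec179",  0, 0, 0, 1, 1, 0, 0, 0,
    "Wec181",  0, 0, 0, 1, 1, 0, 0, 0,
    "Wec186",  0, 0, 0, 1, 1, 0, 0, 0,
    "Wec187",  0, 0, 1, 0, 0, 0, 0, 0,
    "Wec188",  0, 0, 0, 1, 0, 1, 0, 0,
    "Wec190",  0, 0, 0, 1, 0, 1, 0, 0,
    "Wec189",  0, 0, 1, 0, 0, 0, 1, 1,
    "Wec191",  0, 0, 1, 0, 0, 0, 1, 1,
    "Wec193",  0, 0, 1, 0, 0, 0, 1, 1,
    "Wec196",  0, 0, 1, 0, 0, 0, 1, 1,
    "Wec270",  0, 0, 1, 0, 0, 0, 1, 1,
    "Wec272",  0, 0, 1, 0, 0, 0, 1, 1,
    "T5",      0, 0, 0, 0, 0, 0, 0, 0
  )
  if (!include_validation) m <- m[!m$phage_id %in% c("Wec270", "Wec272", "T5"), ]
  m
}

#' Published resistant-strain mutation table of the Wec study
#'
#' The 13 phage-resistant mutant strains of the wild-type host, one row per
#' mutated gene (multi-gene mutants occupy several rows), with the role of
#' each gene summarized in `pathway` (`"LPS biosynthesis"`,
#' `"membrane protein"`, `"flagellar regulator"`, `"cellulose biosynthesis"`).
#' Eight of the 13 strains carry at least one LPS-pathway mutation.
#'
#' @return Tibble with columns `strain_id`, `gene_id`, `pathway`.
#' @examples
#' mg <- wec_mutant_genes()
#' # strains with at least one LPS-biosynthesis mutation
#' length(unique(mg$strain_id[mg$pathway == "LPS biosynthesis"]))
#' @export
wec_mutant_genes <- function() {
  tibble::tribble(
    ~strain_id, ~gene_id, ~pathway,
    "R172",   "waaV",   "LPS biosynthesis",
    "R174",   "waaW",   "LPS biosynthesis",
    "R177-1", "waaV",   "LPS biosynthesis",
    "R177-2", "waaV",   "LPS biosynthesis",
    "R177-2", "wecA",   "LPS biosynthesis",
    "R181",   "manB-1", "LPS biosynthesis",
    "R181",   "waaT",   "LPS biosynthesis",
    "R186",   "fihD",   "flagellar regulator",
    "R186",   "bcsG",   "cellulose biosynthesis",
    "R187",   "bcsG",   "cellulose biosynthesis",
    "R188",   "yhaH",   "membrane protein",
    "R189",   "nfrB",   "membrane protein",
    "R189",   "ompA",   "membrane protein",
    "R190",   "waaG",   "LPS biosynthesis",
    "R191",   "nfrB",   "membrane protein",
    "R191",   "tolA",   "membrane protein",
    "R193",   "waaY",   "LPS biosynthesis",
    "R196",   "waaY",   "LPS biosynthesis"
  )
}

#' Published physiological cluster memberships of the Wec phages
#'
#' The four physiological clusters of the 13 original phages (P1-P4) from
#' Gower-distance complete-linkage clustering at the silhouette-optimal
#' k = 4, and the five-cluster solution after adding the validation phages
#' (`Wec270`/`Wec272` joining P1; `T5` alone in P5, k = 5).
#'
#' @param include_validation `TRUE` (default) for the 16-phage memberships,
#'   `FALSE` for the 13 originals.
#' @return Partition tibble with columns `item`, `label`.
#' @export
wec_physiology_partition <- function(include_validation = TRUE) {
  p <- tibble::tribble(
    ~item, ~label,
    "Wec189", "P1", "Wec191", "P1", "Wec193", "P1", "Wec196", "P1",
    "Wec172", "P2", "Wec174", "P2", "Wec177", "P2",
    "Wec179", "P3", "Wec181", "P3", "Wec186", "P3",
    "Wec187", "P4", "Wec188", "P4", "Wec190", "P4",
    "Wec270", "P1", "Wec272", "P1",
    "T5", "P5"
  )
  if (!include_validation) p <- p[!p$item %in% c("Wec270", "Wec272", "T5"), ]
  p
}

#' Receptor-type partition of the Wec phages
#'
#' Convenience wrapper: runs [assign_receptor_types()] on
#' [wec_receptor_matrix()] and returns the result as a partition tibble
#' (`item`, `label`), suitable for [adjusted_rand()] against the
#' physiological, tail-fiber or whole-genome schemes.
#'
#' @inheritParams wec_receptor_matrix
#' @return Partition tibble with columns `item`, `label` (type letters).
#' @export
wec_receptor_partition <- function(include_validation = TRUE) {
  typing <- assign_receptor_types(wec_receptor_matrix(include_validation))
  tibble::tibble(item = typing$phage_id, label = typing$type)
}
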