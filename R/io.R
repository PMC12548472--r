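#' Read a phage-by-strain infection matrix
#'
#' Reads a delimited table whose first column holds phage identifiers, whose
#' header row holds strain identifiers, and whose cells are 0/1 infection
#' calls (1 = the phage infects the strain). Row and column order of the file
#' is preserved; downstream tie-breaking (e.g. in [greedy_panel()]) depends
#' on it.
#'
#' @param path Path to a CSV or TSV file.
#' @param delim Field delimiter. Defaults to `"\t"` for `.tsv`/`.txt` files
#'   and `","` otherwise.
#' @return A tibble with a `phage_id` character column followed by one 0/1
#'   integer column per strain.
#' @export
read_infection_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  names(raw)[1L] <- "phage_id"
  validate_infection_matrix(raw, where = path)
}

#' Write an infection matrix
#'
#' Inverse of [read_infection_matrix()]; a write/read round trip reproduces
#' the matrix exactly.
#'
#' @param x Infection matrix tibble (`phage_id` + 0/1 strain columns).
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `x`, invisibly.
#' @export
write_infection_matrix <- function(x, path, delim = "\t") {
  x <- validate_infection_matrix(x, where = "x")
  readr::write_delim(x, path, delim = delim)
  invisible(x)
}

validate_infection_matrix <- function(x, where = "infection matrix") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop(sprintf("%s: need a phage_id column plus at least one strain column", where),
         call. = FALSE)
  }
  phage_id <- as.character(x[[1L]])
  strains <- names(x)[-1L]
  if (anyDuplicated(phage_id)) {
    stop(sprintf("%s: duplicate phage ids: %s", where,
                 paste(unique(phage_id[duplicated(phage_id)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyDuplicated(strains)) {
    stop(sprintf("%s: duplicate strain ids: %s", where,
                 paste(unique(strains[duplicated(strains)]), collapse = ", ")),
         call. = FALSE)
  }
  vals <- lapply(x[-1L], function(col) {
    if (is.logical(col)) return(as.integer(col))
    suppressWarnings(as.numeric(as.character(col)))
  })
  for (j in seq_along(vals)) {
    bad <- which(is.na(vals[[j]]) | !(vals[[j]] %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("%s: non-binary cell at phage '%s', strain '%s' (value '%s')",
                   where, phage_id[bad[1L]], strains[j],
                   as.character(x[[j + 1L]][bad[1L]])),
           call. = FALSE)
    }
  }
  out <- tibble::as_tibble(c(list(phage_id = phage_id),
                             lapply(vals, as.integer)))
  names(out) <- c("phage_id", strains)
  out
}

guess_delim <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a long table of spot-test titer observations
#'
#' Expects columns `phage_id`, `strain_id`, `replicate`, `titer`. Titers are
#' PFU-equivalent counts; the literal token `ND` (case-insensitive, "not
#' detected": no plaques at any dilution) is parsed to `NA`, which the EoP
#' functions treat as complete loss of infectivity, not as missing data.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter (guessed from the extension by default).
#' @return A tibble with columns `phage_id`, `strain_id`, `replicate` (int),
#'   `titer` (double, `NA` = ND).
#' @export
read_titer_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  need <- c("phage_id", "strain_id", "replicate", "titer")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  titer_chr <- trimws(raw$titer)
  is_nd <- toupper(titer_chr) == "ND"
  titer <- suppressWarnings(as.numeric(titer_chr))
  bad <- which(!is_nd & (is.na(titer) | titer < 0))
  if (length(bad)) {
    stop(sprintf("%s: row %d: titer must be a nonnegative number or 'ND' (got '%s')",
                 path, bad[1L], titer_chr[bad[1L]]), call. = FALSE)
  }
  titer[is_nd] <- NA_real_
  out <- tibble::tibble(
    phage_id = as.character(raw$phage_id),
    strain_id = as.character(raw$strain_id),
    replicate = as.integer(raw$replicate),
    titer = titer
  )
  key <- paste(out$phage_id, out$strain_id, out$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicate (phage_id, strain_id, replicate) observations", path),
         call. = FALSE)
  }
  out
}

#' Read a mutant-strain to mutated-gene map
#'
#' Expects columns `strain_id` and `gene_id`; one row per mutated gene, so
#' multi-gene knockouts occupy several rows. Extra columns are preserved.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter (guessed from the extension by default).
#' @return A tibble with at least `strain_id` and `gene_id`.
#' @export
read_mutant_genes <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  need <- c("strain_id", "gene_id")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(raw$gene_id) | is.na(raw$gene_id))) {
    stop(sprintf("%s: empty gene identifiers", path), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Read a mixed phenotype table
#'
#' First column = phage identifiers; remaining columns are features, either
#' binary (0/1) or quantitative. Empty cells and the token `NA` become
#' missing values, handled downstream by pairwise deletion in [gower_dist()].
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter (guessed from the extension by default).
#' @return A tibble with `phage_id` plus numeric feature columns.
#' @export
read_phenotype_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  delim <- delim %||% guess_delim(path)
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE, show_col_types = FALSE)
  names(raw)[1L] <- "phage_id"
  feats <- lapply(setNames(names(raw)[-1L], names(raw)[-1L]), function(nm) {
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in feature '%s' (phage '%s')",
                   path, raw[[nm]][bad[1L]], nm, raw$phage_id[bad[1L]]),
           call. = FALSE)
    }
    v
  })
  out <- tibble::as_tibble(c(list(phage_id = as.character(raw$phage_id)), feats))
  names(out) <- names(raw)
  if (anyDuplicated(out$phage_id)) {
    stop(sprintf("%s: duplicate phage ids", path), call. = FALSE)
  }
  out
}

#' Read and write partitions
#'
#' A partition assigns every item exactly one opaque label. On disk a
#' partition is either a two-column TSV/CSV (`item`, `label`) or a JSON
#' object mapping item to label.
#'
#' @param path Input/output path; format chosen by extension (`.json` vs
#'   delimited).
#' @return `read_partition()` returns a tibble with columns `item`, `label`.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    p <- tibble::tibble(item = names(obj), label = as.character(unlist(obj)))
  } else {
    raw <- readr::read_delim(path, delim = guess_delim(path),
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE, show_col_types = FALSE)
    p <- raw
  }
  as_partition(p, arg = path)
}

#' @rdname read_partition
#' @param partition A partition data frame (item column + label column).
#' @export
write_partition <- function(partition, path) {
  p <- as_partition(partition)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(setNames(p$label, p$item)), path,
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    readr::write_delim(p, path, delim = guess_delim(path))
  }
  invisible(p)
}

#' Read a single phylogenetic tree in Newick format
#'
#' Thin validating wrapper around [ape::read.tree()]: exactly one tree, all
#' leaf names unique, and every edge carries a branch length (required by
#' [patristic_dist()]; no silent default is substituted).
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1L]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1L]] == ")", -1L, 0L)))
  if (length(depth) && (any(depth < 0L) || depth[length(depth)] != 0L)) {
    pos <- if (any(depth < 0L)) which(depth < 0L)[1L] else length(depth)
    stop(sprintf("%s: unbalanced parentheses near character %d", path, pos),
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop(sprintf("%s: Newick parse error: %s",
                                                    path, conditionMessage(e)),
                                            call. = FALSE))
  if (is.null(tree)) stop(sprintf("%s: Newick parse error", path), call. = FALSE)
  if (inherits(tree, "multiPhylo")) {
    stop(sprintf("%s: expected a single tree, found %d", path, length(tree)),
         call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop(sprintf("%s: duplicate leaf name(s): %s", path,
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop(sprintf("%s: missing branch length(s); patristic distances need lengths on every edge",
                 path), call. = FALSE)
  }
  tree
}
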