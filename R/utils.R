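# internal helpers shared across modules

# letters, then aa, ab, ... for >26 groups
type_letters <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  extra <- n - 26L
  two <- as.vector(t(outer(letters, letters, paste0)))
  c(letters, two[seq_len(extra)])
}

# coerce a two-column data frame (item, label) into a canonical partition tibble
as_partition <- function(x, arg = "partition") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    stop(sprintf("`%s` must be a data frame with an item column and a label column", arg),
         call. = FALSE)
  }
  id_col <- intersect(c("phage_id", "item_id", "item", "id"), names(x))
  lab_col <- intersect(c("label", "type", "cluster", "group"), names(x))
  id_col <- if (length(id_col)) id_col[[1L]] else names(x)[[1L]]
  lab_col <- if (length(lab_col)) lab_col[[1L]] else setdiff(names(x), id_col)[[1L]]
  out <- tibble::tibble(
    item = as.character(x[[id_col]]),
    label = as.character(x[[lab_col]])
  )
  if (anyDuplicated(out$item)) {
    stop(sprintf("`%s` labels some items more than once: %s", arg,
                 paste(unique(out$item[duplicated(out$item)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(out$label)) {
    stop(sprintf("`%s` contains missing labels", arg), call. = FALSE)
  }
  out
}

# square symmetric matrix with labels from a dist or matrix input
as_dist_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else if (is.matrix(d)) {
    m <- d
  } else {
    stop(sprintf("`%s` must be a `dist` object or a square numeric matrix", arg),
         call. = FALSE)
  }
  if (nrow(m) != ncol(m)) {
    stop(sprintf("`%s` is not square", arg), call. = FALSE)
  }
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE))) {
    stop(sprintf("`%s` is not symmetric", arg), call. = FALSE)
  }
  if (any(m < 0)) {
    stop(sprintf("`%s` contains negative dissimilarities", arg), call. = FALSE)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("item", seq_len(nrow(m)))
  }
  m
}

choose2 <- function(x) x * (x - 1) / 2

# run `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}
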