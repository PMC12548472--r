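#' Gower distance for mixed phenotype tables
#'
#' Computes pairwise Gower dissimilarities
#' \deqn{d_{ij} = \sum_f w_f \delta_f(i,j) / \sum_f w_f}
#' over the features observed in both items. Binary features contribute a
#' 0/1 mismatch; quantitative features contribute the absolute difference
#' scaled by the feature's observed range. Features with zero range
#' contribute \eqn{\delta = 0} (but still count in the weight sum), and
#' missing cells are handled by pairwise deletion with weight
#' renormalization. Distances are bounded in \[0, 1\].
#'
#' @param data Tibble whose first column is `phage_id` and whose remaining
#'   columns are numeric features; `NA` marks a missing cell.
#' @param kinds Optional named character vector declaring each feature as
#'   `"binary"` or `"quantitative"`. By default, columns whose non-missing
#'   values are all 0/1 are binary, the rest quantitative.
#' @param weights Optional named nonnegative feature weights (default 1).
#' @return A [stats::dist] object labelled by `phage_id`.
#' @examples
#' tbl <- tibble::tibble(phage_id = c("p1", "p2"),
#'                       b1 = c(0, 1), b2 = c(1, 1), q = c(0, 5))
#' gower_dist(tbl)  # (1 + 0 + 5/5) / 3 ... ranges computed over the data
#' @export
gower_dist <- function(data, kinds = NULL, weights = NULL) {
  data <- tibble::as_tibble(data)
  if (ncol(data) < 2L) stop("`data` needs an id column plus at least one feature", call. = FALSE)
  if (nrow(data) < 2L) stop("need at least two phages", call. = FALSE)
  ids <- as.character(data[[1L]])
  if (anyDuplicated(ids)) stop("duplicate phage ids", call. = FALSE)
  feats <- names(data)[-1L]
  X <- as.matrix(data[-1L])
  if (!is.numeric(X)) stop("feature columns must be numeric (recode categories as 0/1)", call. = FALSE)

  inferred <- vapply(feats, function(f) {
    v <- X[, f]
    v <- v[!is.na(v)]
    if (length(v) && all(v %in% c(0, 1))) "binary" else "quantitative"
  }, character(1L))
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), feats)
    if (length(bad)) stop(sprintf("`kinds` names unknown feature(s): %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    if (!all(kinds %in% c("binary", "quantitative"))) {
      stop("`kinds` values must be 'binary' or 'quantitative'", call. = FALSE)
    }
    inferred[names(kinds)] <- kinds
    for (f in names(kinds)[kinds == "binary"]) {
      v <- X[, f]
      if (!all(v[!is.na(v)] %in% c(0, 1))) {
        stop(sprintf("feature '%s' declared binary but has values outside {0,1}", f),
             call. = FALSE)
      }
    }
  }
  w <- setNames(rep(1, length(feats)), feats)
  if (!is.null(weights)) {
    bad <- setdiff(names(weights), feats)
    if (length(bad)) stop(sprintf("`weights` names unknown feature(s): %s",
                                  paste(bad, collapse = ", ")), call. = FALSE)
    if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
    w[names(weights)] <- weights
  }

  n <- nrow(X)
  dsum <- matrix(0, n, n)
  wsum <- matrix(0, n, n)
  for (f in feats) {
    v <- X[, f]
    present <- !is.na(v)
    both <- outer(present, present, `&`)
    if (inferred[[f]] == "binary") {
      delta <- outer(v, v, `!=`) * 1
    } else {
      rng <- diff(range(v, na.rm = TRUE))
      delta <- if (rng > 0) abs(outer(v, v, `-`)) / rng else matrix(0, n, n)
    }
    delta[!both] <- 0
    dsum <- dsum + w[[f]] * delta
    wsum <- wsum + w[[f]] * both
  }
  off <- which(wsum == 0 & upper.tri(wsum), arr.ind = TRUE)
  if (nrow(off)) {
    stop(sprintf("phages '%s' and '%s' share no observed feature with positive weight",
                 ids[off[1L, 1L]], ids[off[1L, 2L]]), call. = FALSE)
  }
  d <- dsum / wsum
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  as.dist(d)
}
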