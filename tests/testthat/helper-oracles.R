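# Independent brute-force oracles. These deliberately re-derive each quantity
# from its definition with explicit loops, staying independent of the package
# code paths they check.

# Gower dissimilarity for one pair, looping over features
oracle_gower_pair <- function(X, kinds, w, i, j) {
  num <- 0; den <- 0
  for (f in seq_len(ncol(X))) {
    xi <- X[i, f]; xj <- X[j, f]
    if (is.na(xi) || is.na(xj)) next
    if (kinds[f] == "binary") {
      delta <- as.numeric(xi != xj)
    } else {
      rng <- max(X[, f], na.rm = TRUE) - min(X[, f], na.rm = TRUE)
      delta <- if (rng > 0) abs(xi - xj) / rng else 0
    }
    num <- num + w[f] * delta
    den <- den + w[f]
  }
  num / den
}

oracle_gower <- function(X, kinds, w = rep(1, ncol(X))) {
  n <- nrow(X)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) m[i, j] <- oracle_gower_pair(X, kinds, w, i, j)
  }
  m
}

# average silhouette width from the definition
oracle_silhouette <- function(m, labels) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (length(mates) == 0L) { s[i] <- 0; next }
    a <- mean(m[i, mates])
    b <- Inf
    for (cl in setdiff(unique(labels), own)) {
      b <- min(b, mean(m[i, labels == cl]))
    }
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# naive complete-linkage agglomeration, recomputing every cluster-pair
# distance from the raw matrix at each step; returns merge heights and the
# membership vector after each merge
oracle_complete_linkage <- function(m) {
  n <- nrow(m)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1L)
  partitions <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      d <- max(m[clusters[[i]], clusters[[j]]])
      if (d < best_d) { best_d <- d; best <- c(i, j) }
    }
    heights[step] <- best_d
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- c(clusters[-best], list(merged))
    memb <- integer(n)
    for (ci in seq_along(clusters)) memb[clusters[[ci]]] <- ci
    partitions[[step]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# all-pairs path lengths on the tree graph by Floyd-Warshall
oracle_patristic <- function(tree) {
  n_nodes <- max(tree$edge)
  d <- matrix(Inf, n_nodes, n_nodes)
  diag(d) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    d[a, b] <- d[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(n_nodes)) for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  tips <- seq_along(tree$tip.label)
  out <- d[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# ARI from pair counting: classify every item pair as co-clustered in both,
# one, or neither partition
oracle_ari <- function(l1, l2) {
  n <- length(l1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same1 <- l1[i] == l1[j]; same2 <- l2[i] == l2[j]
    if (same1 && same2) n11 <- n11 + 1
    else if (same1 && !same2) n10 <- n10 + 1
    else if (!same1 && same2) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# receptor-profile inference re-derived directly from the stated rule,
# one phage at a time with explicit set operations
oracle_receptor_row <- function(blocking_sets, nonblocking_sets) {
  candidates <- unique(as.character(unlist(blocking_sets)))
  exonerated <- character(0)
  for (nb in nonblocking_sets) {
    subset_of_blocking <- FALSE
    for (b in blocking_sets) if (all(nb %in% b)) subset_of_blocking <- TRUE
    if (subset_of_blocking) exonerated <- unique(c(exonerated, nb))
  }
  required <- setdiff(candidates, exonerated)
  resolved <- character(0)
  for (b in blocking_sets) {
    eff <- setdiff(b, exonerated)
    if (length(eff) == 1L) resolved <- c(resolved, eff)
  }
  list(required = required, ambiguous = setdiff(required, resolved))
}
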