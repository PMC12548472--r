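test_that("Gower distance follows the per-feature formula", {
  # identical rows are at distance zero
  same <- tibble::tibble(phage_id = c("a", "b"), f1 = c(1, 1), f2 = c(2.5, 2.5))
  expect_equal(as.vector(gower_dist(same)), 0)

  # binary mismatch + binary match + quantitative diff 5 over range 10
  tbl <- tibble::tibble(
    phage_id = c("a", "b", "c"),
    bin_mis = c(0, 1, 1), bin_match = c(1, 1, 1), quant = c(0, 5, 10)
  )
  d <- as.matrix(gower_dist(tbl))
  expect_equal(d["a", "b"], (1 + 0 + 0.5) / 3)

  # zero-range quantitative features contribute delta = 0 but keep weight
  zr <- tibble::tibble(phage_id = c("a", "b"), b1 = c(0, 1), q = c(3, 3))
  expect_equal(as.vector(gower_dist(zr)), 0.5)
})

test_that("Gower matches the per-pair loop oracle on random mixed tables", {
  withr::local_seed(101)
  for (n in c(6, 12, 50)) {
    tbl <- random_phenotypes(n, n_bin = 3, n_quant = 2, p_na = 0.15)
    kinds <- c(rep("binary", 3), rep("quantitative", 2))
    w <- runif(5, 0.5, 2)
    got <- as.matrix(gower_dist(tbl, weights = setNames(w, names(tbl)[-1])))
    want <- oracle_gower(as.matrix(tbl[, -1]), kinds, w)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("Gower output permutes consistently with its rows", {
  withr::local_seed(7)
  tbl <- random_phenotypes(8, p_na = 0)
  d <- as.matrix(gower_dist(tbl))
  perm <- sample(8)
  d2 <- as.matrix(gower_dist(tbl[perm, ]))
  expect_equal(d2, d[perm, perm][rownames(d2), colnames(d2)], tolerance = 1e-14)
})

test_that("pairs sharing no observed feature are rejected by name", {
  tbl <- tibble::tibble(phage_id = c("a", "b"), f1 = c(1, NA), f2 = c(NA, 0))
  expect_error(gower_dist(tbl), "'a' and 'b'")
})

test_that("complete linkage reproduces hand-checkable merges", {
  # two tight pairs merge first at 0.1
  m <- matrix(0.9, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.1
  m[3, 4] <- m[4, 3] <- 0.1
  diag(m) <- 0
  dimnames(m) <- list(letters[1:4], letters[1:4])
  hc <- hclust_complete(m)
  expect_equal(hc$height[1:2], c(0.1, 0.1))
  expect_equal(sort(cut_k(hc, 2)$label[match(c("a", "b"), letters[1:4])]),
               sort(cut_k(hc, 2)$label[1:2]))
  part2 <- cut_k(hc, 2)
  expect_equal(part2$label[1], part2$label[2])
  expect_equal(part2$label[3], part2$label[4])
  expect_false(part2$label[1] == part2$label[3])
})

test_that("complete linkage agrees with the naive oracle and with stats::hclust", {
  withr::local_seed(202)
  for (n in c(4, 8, 20, 40)) {
    m <- random_dist(n)
    hc <- hclust_complete(m)
    expect_true(all(diff(hc$height) >= -1e-12))
    oracle <- oracle_complete_linkage(m)
    expect_lt(max(abs(hc$height - oracle$heights)), 1e-12)
    ref <- stats::hclust(as.dist(m), method = "complete")
    expect_lt(max(abs(sort(hc$height) - sort(ref$height))), 1e-12)
    for (k in c(2, min(5, n - 1))) {
      mine <- cut_k(hc, k)
      theirs <- tibble::tibble(item = rownames(m),
                               label = as.character(cutree(ref, k)))
      expect_equal(adjusted_rand(mine, theirs), 1)
      orc <- oracle$partitions[[n - k]]
      expect_equal(adjusted_rand(mine, tibble::tibble(item = rownames(m),
                                                      label = as.character(orc))), 1)
    }
  }
})

test_that("cut_k covers the degenerate cuts and validates k", {
  m <- random_dist(5)
  hc <- hclust_complete(m)
  expect_equal(length(unique(cut_k(hc, 1)$label)), 1L)
  expect_equal(length(unique(cut_k(hc, 5)$label)), 5L)
  expect_error(cut_k(hc, 0), "between")
  expect_error(cut_k(hc, 6), "between")
  # partitions are nested as k decreases
  p3 <- cut_k(hc, 3); p2 <- cut_k(hc, 2)
  for (lab in unique(p3$label)) {
    members <- p3$item[p3$label == lab]
    expect_equal(length(unique(p2$label[p2$item %in% members])), 1L)
  }
})

test_that("silhouette matches hand values, conventions, and the oracle", {
  # two clusters, within 0, between 1 -> average 1
  m <- matrix(1, 4, 4)
  m[1, 2] <- m[2, 1] <- 0
  m[3, 4] <- m[4, 3] <- 0
  diag(m) <- 0
  dimnames(m) <- list(paste0("i", 1:4), paste0("i", 1:4))
  p <- tibble::tibble(item = paste0("i", 1:4), label = c("A", "A", "B", "B"))
  expect_equal(silhouette_avg(m, p), 1)

  # two singletons -> both s = 0 -> average 0
  m2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  p2 <- tibble::tibble(item = c("x", "y"), label = c("A", "B"))
  expect_equal(silhouette_avg(m2, p2), 0)
  expect_error(silhouette_avg(m2, tibble::tibble(item = c("x", "y"), label = c("A", "A"))),
               "two clusters")

  withr::local_seed(303)
  for (n in c(7, 15, 50)) {
    m <- random_dist(n)
    labels <- sample(letters[1:4], n, replace = TRUE)
    part <- tibble::tibble(item = rownames(m), label = labels)
    if (length(unique(labels)) < 2) next
    expect_equal(silhouette_avg(m, part), oracle_silhouette(m, labels),
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with cluster::silhouette on random instances", {
  withr::local_seed(404)
  for (rep_i in 1:5) {
    n <- sample(6:20, 1)
    m <- random_dist(n)
    labels <- sample(1:3, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    sil <- cluster::silhouette(labels, dmatrix = m)
    ref <- mean(sil[, "sil_width"])
    part <- tibble::tibble(item = rownames(m), label = as.character(labels))
    expect_equal(silhouette_avg(m, part), ref, tolerance = 1e-12)
  }
})

test_that("select_k sweeps the dendrogram cuts and takes the smallest argmax", {
  # two perfectly separated blobs -> k = 2
  tbl <- tibble::tibble(phage_id = paste0("p", 1:6),
                        f1 = c(0, 0, 0, 1, 1, 1), f2 = c(0, 0, 0, 1, 1, 1),
                        f3 = c(0.1, 0.2, 0.15, 3.1, 3.2, 3.15))
  sw <- select_k(gower_dist(tbl))
  expect_equal(attr(sw, "chosen_k"), 2L)

  # sweep values equal per-k recomputation
  withr::local_seed(505)
  m <- random_dist(12)
  sw2 <- select_k(m, 2, 6)
  hc <- hclust_complete(m)
  for (i in seq_len(nrow(sw2))) {
    expect_equal(sw2$avg_silhouette[i],
                 silhouette_avg(m, cut_k(hc, sw2$k[i])), tolerance = 1e-14)
  }
  expect_error(select_k(m, 1, 5), "k_min")
  expect_error(select_k(m, 2, 12), "k_min|n - 1")
})

test_that("select_k recovers planted groups with zero within-group variance", {
  withr::local_seed(606)
  for (k_true in c(3, 4)) {
    n <- 3 * k_true
    centers <- matrix(rnorm(k_true * 4, sd = 4), k_true, 4)
    X <- centers[rep(seq_len(k_true), each = 3), ]
    tbl <- dplyr::bind_cols(tibble::tibble(phage_id = paste0("p", seq_len(n))),
                            tibble::as_tibble(as.data.frame(X)))
    sw <- select_k(gower_dist(tbl))
    expect_equal(attr(sw, "chosen_k"), k_true)
  }
})

test_that("patristic distances sum branch lengths along paths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- as.matrix(patristic_dist(tr))
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)

  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  ds <- as.matrix(patristic_dist(star))
  expect_true(all(ds[upper.tri(ds)] == 6))

  neg <- ape::read.tree(text = "((A:1,B:-1):1,C:2);")
  expect_error(patristic_dist(neg), "negative")
})

test_that("patristic distances match Floyd-Warshall and satisfy the four-point condition", {
  withr::local_seed(707)
  for (n in c(5, 8, 12)) {
    tr <- ape::rtree(n)
    d <- as.matrix(patristic_dist(tr))
    want <- oracle_patristic(tr)[rownames(d), colnames(d)]
    expect_lt(max(abs(d - want)), 1e-10)
    # four-point condition on random leaf quadruples
    for (rep_i in 1:10) {
      q <- sample(rownames(d), 4)
      sums <- c(d[q[1], q[2]] + d[q[3], q[4]],
                d[q[1], q[3]] + d[q[2], q[4]],
                d[q[1], q[4]] + d[q[2], q[3]])
      top2 <- sort(sums, decreasing = TRUE)[1:2]
      expect_lt(abs(top2[1] - top2[2]), 1e-8)
    }
  }
})

test_that("cluster_phages chains distance, sweep, and cut", {
  withr::local_seed(808)
  tbl <- random_phenotypes(10, p_na = 0)
  cl <- cluster_phages(gower_dist(tbl))
  expect_s3_class(cl, "phage_clustering")
  expect_equal(sort(cl$partition$item), sort(tbl$phage_id))
  expect_equal(length(unique(cl$partition$label)), cl$k)
  fixed <- cluster_phages(gower_dist(tbl), k = 3)
  expect_equal(fixed$k, 3L)
  expect_null(fixed$sweep)
})
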