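make_reduction <- function(phage, calls) {
  tibble::tibble(phage_id = phage, strain_id = names(calls),
                 reduced = unname(calls))
}

test_that("a shared-gene non-blocking strain exonerates its gene", {
  # double mutant {flhD, bcsG} blocks; single {bcsG} does not -> only flhD required
  genes <- tibble::tibble(strain_id = c("R186", "R186", "R187"),
                          gene_id = c("flhD", "bcsG", "bcsG"))
  prof <- derive_receptor_profile(
    make_reduction("X", c(R186 = TRUE, R187 = FALSE)), genes
  )
  wide <- profile_matrix(prof)
  expect_equal(wide$flhD, 1L)
  expect_equal(wide$bcsG, 0L)
  expect_false(any(prof$ambiguous))
})

test_that("a phage blocked by no strain gets an all-zero row", {
  genes <- tibble::tibble(strain_id = c("s1", "s2"), gene_id = c("gA", "gB"))
  prof <- derive_receptor_profile(
    make_reduction("T5like", c(s1 = FALSE, s2 = FALSE)), genes
  )
  expect_equal(prof$required, c(0L, 0L))
})

test_that("inseparable multi-gene mutants leave all their genes required and flagged", {
  genes <- tibble::tibble(strain_id = c("d1", "d1", "d2", "d2"),
                          gene_id = c("nfrB", "ompA", "nfrB", "tolA"))
  prof <- derive_receptor_profile(
    make_reduction("X", c(d1 = TRUE, d2 = TRUE)), genes
  )
  expect_equal(sum(prof$required), 3L)
  expect_true(all(prof$ambiguous[prof$required == 1L]))
})

test_that("profile inference matches the rule-based oracle over all call patterns", {
  # fixed strain design: singles, a nested double, and an overlapping double
  strain_sets <- list(s1 = "g1", s2 = "g2", d12 = c("g1", "g2"), d23 = c("g2", "g3"))
  genes <- tibble::tibble(strain_id = rep(names(strain_sets), lengths(strain_sets)),
                          gene_id = unlist(strain_sets, use.names = FALSE))
  for (mask in 0:15) {
    calls <- as.logical(bitwAnd(mask, c(1L, 2L, 4L, 8L)) > 0)
    names(calls) <- names(strain_sets)
    prof <- derive_receptor_profile(make_reduction("X", calls), genes)
    expect_oracle <- oracle_receptor_row(strain_sets[calls], strain_sets[!calls])
    expect_setequal(prof$gene_id[prof$required == 1L], expect_oracle$required)
    expect_setequal(prof$gene_id[prof$ambiguous], expect_oracle$ambiguous)
  }
})

test_that("adding a non-blocking single-gene strain never sets a requirement bit", {
  withr::local_seed(11)
  strain_sets <- list(a = c("g1", "g2"), b = "g2", c = c("g2", "g3"))
  genes <- tibble::tibble(strain_id = rep(names(strain_sets), lengths(strain_sets)),
                          gene_id = unlist(strain_sets, use.names = FALSE))
  for (rep_i in 1:20) {
    calls <- setNames(sample(c(TRUE, FALSE), 3, replace = TRUE), names(strain_sets))
    before <- derive_receptor_profile(make_reduction("X", calls), genes)
    genes2 <- dplyr::bind_rows(genes, tibble::tibble(strain_id = "new", gene_id = "g1"))
    after <- derive_receptor_profile(
      make_reduction("X", c(calls, new = FALSE)), genes2
    )
    after <- after[after$gene_id %in% before$gene_id, ]
    expect_true(all(after$required <= before$required))
  }
})

test_that("overrides set bits last and clear ambiguity flags", {
  genes <- tibble::tibble(strain_id = c("d1", "d1"), gene_id = c("gA", "gB"))
  ov <- tibble::tibble(phage_id = "X", gene_id = "gB", value = 0)
  prof <- derive_receptor_profile(make_reduction("X", c(d1 = TRUE)), genes,
                                  overrides = ov)
  wide <- profile_matrix(prof)
  expect_equal(wide$gA, 1L)
  expect_equal(wide$gB, 0L)
  expect_false(any(prof$ambiguous[prof$gene_id == "gB"]))
  expect_error(
    derive_receptor_profile(make_reduction("X", c(d1 = TRUE)), genes,
                            overrides = tibble::tibble(phage_id = "X", gene_id = "zz", value = 1)),
    "unknown"
  )
})

test_that("a strain absent from the gene map is reported by name", {
  genes <- tibble::tibble(strain_id = "s1", gene_id = "gA")
  expect_error(
    derive_receptor_profile(make_reduction("X", c(s1 = TRUE, mystery = FALSE)), genes),
    "mystery"
  )
})

test_that("receptor types letter identical rows in order of first appearance", {
  prof <- tibble::tibble(phage_id = c("p1", "p2", "p3", "p4"),
                         gA = c(1, 0, 1, 0), gB = c(0, 1, 0, 1))
  ty <- assign_receptor_types(prof)
  expect_equal(ty$type, c("a", "b", "a", "b"))

  all_same <- tibble::tibble(phage_id = c("x", "y"), g = c(1, 1))
  expect_equal(assign_receptor_types(all_same)$type, c("a", "a"))
  expect_error(assign_receptor_types(prof, phages = "nope"), "unknown phage")
})

test_that("typing is stable under row duplication and equivariant under reordering", {
  withr::local_seed(5)
  prof <- tibble::tibble(phage_id = paste0("p", 1:6),
                         gA = rbinom(6, 1, 0.5), gB = rbinom(6, 1, 0.5),
                         gC = rbinom(6, 1, 0.5))
  ty <- assign_receptor_types(prof)
  # duplicate a row: the twin gets the same letter
  dup <- dplyr::bind_rows(prof, dplyr::mutate(prof[3, ], phage_id = "p3bis"))
  ty_dup <- assign_receptor_types(dup)
  expect_equal(ty_dup$type[ty_dup$phage_id == "p3bis"],
               ty_dup$type[ty_dup$phage_id == "p3"])
  # reordering only renames letters: same partition up to relabeling
  perm <- sample(nrow(prof))
  ty_perm <- assign_receptor_types(prof[perm, ])
  p1 <- tibble::tibble(item = ty$phage_id, label = ty$type)
  p2 <- tibble::tibble(item = ty_perm$phage_id, label = ty_perm$type)
  expect_equal(adjusted_rand(p1, p2), 1)
  # type count equals the number of distinct rows (hash oracle)
  expect_equal(length(unique(ty$type)),
               nrow(unique(prof[, -1])))
})
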