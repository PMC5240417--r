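pairs_df <- function(...) {
  m <- matrix(c(..., character()), ncol = 4, byrow = TRUE)
  data.frame(species_a = m[, 1], gene_a = m[, 2],
             species_b = m[, 3], gene_b = m[, 4], stringsAsFactors = FALSE)
}

test_that("groups are connected components with singleton fill-in", {
  uni <- list(A = c("A1", "A2"), B = "B1", C = "C1")
  g <- build_groups(pairs_df("A", "A1", "B", "B1", "B", "B1", "C", "C1"), uni)
  trio <- g[!is.na(g$A) & g$A == "A1", ]
  expect_identical(unname(unlist(trio[, c("A", "B", "C")])),
                   c("A1", "B1", "C1"))
  single <- g[!is.na(g$A) & g$A == "A2", ]
  expect_true(all(is.na(single[, c("B", "C")])))
  expect_identical(nrow(g), 2L)
})

test_that("an empty pair list yields one singleton group per unigene", {
  uni <- list(A = c("A1", "A2"), B = c("B1", "B2"), C = c("C1", "C2"))
  g <- build_groups(pairs_df()[0, ], uni)
  expect_identical(nrow(g), 6L)
  pres <- !is.na(as.matrix(g[, c("A", "B", "C")]))
  expect_true(all(rowSums(pres) == 1))
})

test_that("components match a brute-force BFS oracle on random graphs", {
  for (seed in 1:3) {
    set.seed(seed)
    uni <- list(A = sprintf("A%02d", 1:18), B = sprintf("B%02d", 1:16),
                C = sprintf("C%02d", 1:16))
    all_sp <- rep(names(uni), lengths(uni))
    all_g <- unlist(uni)
    k <- 25
    i <- sample(length(all_g), k, replace = TRUE)
    j <- sample(length(all_g), k, replace = TRUE)
    ok <- all_sp[i] != all_sp[j]
    pr <- data.frame(species_a = all_sp[i][ok], gene_a = all_g[i][ok],
                     species_b = all_sp[j][ok], gene_b = all_g[j][ok],
                     stringsAsFactors = FALSE)
    g <- build_groups(pr, uni)

    comps <- oracle_components(
      data.frame(from = pr$gene_a, to = pr$gene_b), all_g)
    # genes of a multi-member oracle component must share a group unless
    # demoted; verify via the lexicographic resolution rule per species
    for (comp in comps) {
      sp <- substr(comp, 1, 1)
      keepers <- unlist(lapply(split(comp, sp), function(x) sort(x)[1]))
      row_of <- function(gene) which(apply(g[, c("A", "B", "C")], 1,
                                           function(r) gene %in% r))
      expect_identical(length(unique(vapply(keepers, row_of, 0L))), 1L)
      demoted <- setdiff(comp, keepers)
      for (d in demoted) {
        r <- g[row_of(d), c("A", "B", "C")]
        expect_identical(sum(!is.na(r)), 1L)
      }
    }
  }
})

test_that("group membership partitions the unigene union", {
  set.seed(8)
  uni <- list(A = sprintf("A%02d", 1:20), B = sprintf("B%02d", 1:20),
              C = sprintf("C%02d", 1:20))
  pr <- pairs_df("A", "A01", "B", "B01", "A", "A01", "C", "C01",
                 "A", "A02", "B", "B02", "B", "B03", "C", "C03")
  g <- build_groups(pr, uni)
  for (sp in names(uni)) {
    mem <- g[[sp]][!is.na(g[[sp]])]
    expect_setequal(mem, uni[[sp]])
    expect_false(any(duplicated(mem)))
  }
})

test_that("pairs referencing unknown unigenes are rejected", {
  uni <- list(A = "A1", B = "B1", C = "C1")
  expect_error(build_groups(pairs_df("A", "A9", "B", "B1"), uni),
               "unknown unigene")
})

test_that("count assignment concatenates members and zero-fills singletons", {
  uni <- list(A = c("A1", "A2"), B = "B1", C = "C1")
  g <- build_groups(pairs_df("A", "A1", "B", "B1", "B", "B1", "C", "C1"), uni)
  counts <- list(
    A = matrix(1:4, 2, 2, dimnames = list(c("A1", "A2"), c("a1", "a2"))),
    B = matrix(5:6, 1, 2, dimnames = list("B1", c("b1", "b2"))),
    C = matrix(7:8, 1, 2, dimnames = list("C1", c("c1", "c2"))))
  m <- counts_to_groups(g, counts)
  trio_id <- g$group_id[!is.na(g$A) & g$A == "A1"]
  single_id <- g$group_id[!is.na(g$A) & g$A == "A2"]
  expect_identical(unname(m[trio_id, ]), c(1L, 3L, 5L, 6L, 7L, 8L))
  expect_identical(unname(m[single_id, c("b1", "b2", "c1", "c2")]),
                   rep(0L, 4))
  # totals are conserved
  expect_identical(sum(m), sum(vapply(counts, sum, 0L)))
  # a member without counts is an input error
  counts$B <- counts$B[0, , drop = FALSE]
  expect_error(counts_to_groups(g, counts), "without counts")
})

test_that("venn regions partition the groups", {
  uni <- list(A = c("A1", "A2"), B = c("B1", "B2"), C = c("C1", "C2"))
  g0 <- build_groups(pairs_df()[0, ], uni)
  v0 <- venn_counts(g0)
  expect_identical(unname(v0["union"]), 6L)
  expect_true(all(v0[c("A+B", "A+C", "B+C", "all_three")] == 0))

  g1 <- build_groups(pairs_df("A", "A1", "B", "B1", "B", "B1", "C", "C1"), uni)
  v1 <- venn_counts(g1)
  expect_identical(unname(v1["all_three"]), 1L)

  for (seed in 1:3) {
    set.seed(seed)
    uni <- list(A = sprintf("A%02d", 1:15), B = sprintf("B%02d", 1:15),
                C = sprintf("C%02d", 1:15))
    idx <- sample(15, 8)
    pr <- rbind(pairs_df(), data.frame(
      species_a = "A", gene_a = sprintf("A%02d", idx),
      species_b = sample(c("B", "C"), 8, replace = TRUE),
      gene_b = sprintf("%s%02d", sample(c("B", "C"), 8, replace = TRUE), idx),
      stringsAsFactors = FALSE))
    pr$gene_b <- paste0(pr$species_b, substr(pr$gene_b, 2, 3))
    g <- build_groups(pr, uni)
    v <- venn_counts(g)
    expect_identical(sum(v[setdiff(names(v), "union")]),
                     unname(v[["union"]]))
    expect_identical(unname(v[["union"]]), nrow(g))
  }
})
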