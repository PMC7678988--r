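test_that("single-linkage ladder matches clade structure on the worked tree", {
  tree <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  cm <- cophenetic_matrix(tree)
  lad <- single_linkage_ladder(cm, c(0, 2, 6))
  expect_equal(lad$n_clusters, c(4L, 2L, 1L))
  p2 <- ladder_partition(lad, 2)
  expect_equal(unname(p2[c("A", "B")]), c("A", "A"))
  expect_equal(unname(p2[c("C", "D")]), c("C", "C"))
  expect_error(single_linkage_ladder(cm, c(2, 0)), "sorted")
})

test_that("threshold zero separates distinct tips and the top threshold merges all", {
  tr <- random_tree(10, seed = 8)
  cm <- cophenetic_matrix(tr)
  lad <- single_linkage_ladder(cm, c(0, max(cm)))
  expect_equal(lad$n_clusters, c(10L, 1L))
  # duplicate tips (zero distance) merge already at t = 0: closed threshold
  dup <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  lad0 <- single_linkage_ladder(dup, 0)
  expect_equal(lad0$n_clusters, 2L)
})

test_that("ladder equals brute-force union-find on random distance matrices", {
  for (i in 1:30) {
    set.seed(900 + i)
    n <- 12
    pts <- matrix(rnorm(n * 2), n)
    d <- as.matrix(dist(pts))
    ids <- sprintf("t%02d", 1:n)
    dimnames(d) <- list(ids, ids)
    ths <- sort(c(0, sample(d[upper.tri(d)], 4)))
    lad <- single_linkage_ladder(d, ths)
    for (l in seq_along(ths)) {
      ours <- lad$membership[, l]
      brute <- brute_components(d, ths[l])
      expect_true(same_partition(ours, brute))
    }
  }
})

test_that("ladder partitions are nested and counts non-increasing", {
  for (i in 1:20) {
    tr <- random_tree(15, seed = 1200 + i)
    cm <- cophenetic_matrix(tr)
    lad <- single_linkage_ladder(cm, agglomeration_thresholds(cm, 10))
    expect_true(all(diff(lad$n_clusters) <= 0))
    for (l in seq_len(length(lad$thresholds) - 1)) {
      fine <- lad$membership[, l]
      coarse <- lad$membership[, l + 1]
      # every fine cluster maps into exactly one coarse cluster
      expect_true(all(tapply(coarse, fine, function(x) length(unique(x))) == 1))
    }
  }
})

test_that("quantile ladders move at every level and span the full range", {
  tr <- random_tree(40, seed = 99)
  cm <- cophenetic_matrix(tr)
  ths <- agglomeration_thresholds(cm, 20)
  expect_equal(ths[1], 0)
  expect_true(all(diff(ths) > 0))
  lad <- single_linkage_ladder(cm, ths)
  expect_equal(lad$n_clusters[1], 40L)
  expect_equal(lad$n_clusters[length(ths)], 1L)
  lin <- agglomeration_thresholds(cm, 20, ladder = "linear")
  expect_equal(single_linkage_ladder(cm, lin)$n_clusters[length(lin)], 1L)
})

test_that("collapsing conserves counts and merges the stated rows", {
  tab <- make_table(list(s1 = c(1, 2, 3), s2 = c(0, 5, 3)), c("A", "B", "C"))
  part <- c(A = "A", B = "A", C = "C")
  col <- collapse_table(tab, part)
  m <- cdiv:::as_count_matrix(col$table)
  expect_equal(m["A", ], c(s1 = 3, s2 = 5))
  expect_equal(m["C", ], c(s1 = 3, s2 = 3))
  expect_equal(colSums(m), colSums(cdiv:::as_count_matrix(tab)))
  expect_equal(col$member_map$A, c("A", "B"))

  # identity and all-in-one partitions
  ident <- collapse_table(tab, c(A = "A", B = "B", C = "C"))
  expect_equal(
    cdiv:::as_count_matrix(ident$table),
    cdiv:::as_count_matrix(tab)
  )
  one <- collapse_table(tab, c(A = "g", B = "g", C = "g"))
  expect_equal(
    as.vector(cdiv:::as_count_matrix(one$table)),
    unname(colSums(cdiv:::as_count_matrix(tab)))
  )
  expect_error(collapse_table(tab, c(A = "A", B = "B")), "misses")
})

test_that("grand totals are conserved across a whole ladder", {
  tr <- random_tree(20, seed = 55)
  tab <- random_table(tr, 4)
  cm <- cophenetic_matrix(tr)
  lad <- single_linkage_ladder(cm, agglomeration_thresholds(cm, 8))
  total <- sum(cdiv:::as_count_matrix(tab))
  for (l in seq_along(lad$thresholds)) {
    col <- collapse_table(tab, ladder_partition(lad, l), level = lad$thresholds[l])
    expect_equal(sum(cdiv:::as_count_matrix(col$table)), total)
  }
})

test_that("rank collapsing groups assigned lineages and isolates unassigned taxa", {
  tab <- make_table(list(s1 = c(1, 2, 3), s2 = c(4, 5, 6)), c("A", "B", "C"))
  tax <- tibble::tibble(
    taxon_id = c("A", "B", "C"),
    domain = "Bacteria",
    phylum = c("P1", "P1", "P2"),
    class = "", order = "",
    family = c("F1", "F1", ""),
    genus = c("G1", "G2", ""),
    species = ""
  )
  fam <- collapse_by_rank(tab, tax, "family")
  expect_equal(nrow(fam$table), 2) # {A,B} share family F1; C unassigned
  gen <- collapse_by_rank(tab, tax, "genus")
  expect_equal(nrow(gen$table), 3)
  phy <- collapse_by_rank(tab, tax, "phylum")
  expect_equal(nrow(phy$table), 2)
  # all lineages empty at rank: identity partition
  tax_empty <- dplyr::mutate(tax, species = "")
  sp <- collapse_by_rank(tab, tax_empty, "species")
  expect_equal(nrow(sp$table), 3)
  expect_error(collapse_by_rank(tab, tax, "kingdom"), "unknown rank")
})

test_that("presence sets apply the count and sample thresholds", {
  tab <- make_table(
    list(
      bsSP_1 = c(5, 0, 1), bsSP_2 = c(2, 0, 0), bsSP_3 = c(1, 0, 0),
      bsCZ_1 = c(0, 1, 1), bsCZ_2 = c(0, 1, 1), bsCZ_3 = c(0, 0, 1)
    ),
    c("A", "B", "C")
  )
  meta <- make_metadata(
    names(tab)[-1],
    rep(c("SP", "CZ"), each = 3),
    "bulk",
    rep(1:3, 2)
  )
  expect_setequal(presence_set(tab, meta, "SP", "bulk"), c("A", "C"))
  expect_setequal(presence_set(tab, meta, "CZ", "bulk"), c("B", "C"))
  # C is seen once in SP: excluded at min_samples = 2
  expect_setequal(presence_set(tab, meta, "SP", "bulk", min_samples = 2), "A")
  # min_count raises the detection bar
  expect_setequal(presence_set(tab, meta, "SP", "bulk", min_count = 2), c("A"))
  expect_error(presence_set(tab, meta, "SP", "culturome"), "no samples")
})
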