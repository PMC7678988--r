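# a 4-taxon fixture with known presence sets: SP = {A,B,C}, CZ = {B,C,D}
divergence_fixture <- function() {
  tab <- make_table(
    list(
      bsSP_1 = c(2, 1, 0, 0), bsSP_2 = c(0, 0, 3, 0),
      bsCZ_1 = c(0, 4, 1, 0), bsCZ_2 = c(0, 0, 0, 2)
    ),
    c("A", "B", "C", "D")
  )
  meta <- make_metadata(
    names(tab)[-1], rep(c("SP", "CZ"), each = 2), "bulk", rep(1:2, 2)
  )
  tree <- ape::read.tree(text = "((A:1,B:1):3,(C:1,D:1):3);")
  list(tab = tab, meta = meta, tree = tree)
}

test_that("divergence curves are direct presence-set arithmetic", {
  fx <- divergence_fixture()
  cm <- cophenetic_matrix(fx$tree)
  lad <- single_linkage_ladder(cm, c(0, 2, 8))
  cur <- divergence_curve(lad, fx$tab, fx$meta, "bulk")
  # leaf level: shared {B,C} of union {A,B,C,D}
  expect_equal(cur$shared_pct[1], 50)
  expect_equal(cur$n_taxa[1], 4)
  # cherry level: SP = {AB, CD}, CZ = {AB, CD} -> identical sets
  expect_equal(cur$shared_pct[2], 100)
  # one-cluster level is always 100 when both soils are populated
  expect_equal(cur$shared_pct[3], 100)
  expect_equal(cur$n_taxa[3], 1)
  expect_error(divergence_curve(lad, fx$tab, fx$meta, "culturome"), "fraction")
})

test_that("disjoint and identical presence sets give 0 and 100", {
  tab <- make_table(
    list(bsSP_1 = c(3, 0), bsSP_2 = c(1, 0), bsCZ_1 = c(0, 2), bsCZ_2 = c(0, 1)),
    c("A", "B")
  )
  meta <- make_metadata(names(tab)[-1], rep(c("SP", "CZ"), each = 2), "bulk")
  tree <- ape::read.tree(text = "(A:1,B:1);")
  lad <- single_linkage_ladder(cophenetic_matrix(tree), c(0, 2))
  cur <- divergence_curve(lad, tab, meta, "bulk")
  expect_equal(cur$shared_pct, c(0, 100))
})

# synthetic curve lying exactly on a line in the merged-fraction x
line_curve <- function(slope, intercept, n0 = 200, levels = 30, fraction = "bulk") {
  n_taxa <- round(seq(n0, 1, length.out = levels))
  x <- 1 - n_taxa / n0
  tibble::tibble(
    fraction = fraction, level = seq_len(levels),
    threshold = seq(0, 2, length.out = levels),
    n_taxa = n_taxa, shared_pct = intercept + slope * x
  )
}

test_that("an exact linear curve is recovered perfectly", {
  cur <- line_curve(47.23, 10)
  fit <- suppressWarnings(fit_divergence_regression(cur, min_taxa = 50))
  expect_equal(fit$slope, 47.23, tolerance = 1e-9)
  expect_equal(fit$intercept, 10, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(all(cur$n_taxa[seq_len(fit$n_points)] >= 50))
})

test_that("a constant curve has zero slope and too few points error out", {
  cur <- line_curve(0, 80)
  fit <- suppressWarnings(fit_divergence_regression(cur, min_taxa = 50))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  short <- line_curve(10, 10, n0 = 60, levels = 4)
  expect_error(fit_divergence_regression(short, min_taxa = 55), "at least 3")
})

test_that("reported slope standard errors match sampling theory", {
  base <- line_curve(30, 20)
  eligible <- base$n_taxa >= 50
  x <- (1 - base$n_taxa / base$n_taxa[1])[eligible]
  sigma <- 4
  analytic_se <- sigma / sqrt(sum((x - mean(x))^2))
  set.seed(1234)
  slopes <- replicate(500, {
    cur <- base
    cur$shared_pct <- 20 + 30 * (1 - cur$n_taxa / cur$n_taxa[1]) +
      rnorm(nrow(cur), 0, sigma)
    fit_divergence_regression(cur, min_taxa = 50)$slope
  })
  expect_lt(abs(sd(slopes) - analytic_se) / analytic_se, 0.15)
})

test_that("slope comparison flags the degenerate identical-curve case", {
  a <- line_curve(40, 10, fraction = "bulk")
  b <- line_curve(40, 10, fraction = "culturome")
  cmp <- compare_slopes(a, b)
  expect_equal(cmp$slope_a, cmp$slope_b, tolerance = 1e-9)
  expect_true(cmp$degenerate)
  expect_true(is.nan(cmp$p_value))
})

test_that("slope comparison detects a large slope gap under noise", {
  set.seed(77)
  a <- line_curve(0, 50)
  a$shared_pct <- a$shared_pct + rnorm(nrow(a), 0, 5)
  b <- line_curve(100, 10, fraction = "culturome")
  b$shared_pct <- b$shared_pct + rnorm(nrow(b), 0, 5)
  cmp <- compare_slopes(a, b)
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$slope_b, cmp$slope_a)
})

test_that("the overlap census reproduces manual set arithmetic", {
  # 6 taxa; presence by construction:
  # bulk SP {A,B,C,D}, bulk CZ {B,C,E}, cult SP {C,D,E}, cult CZ {C,F}
  tab <- make_table(
    list(
      bsSP_1 = c(1, 1, 1, 1, 0, 0), bsSP_2 = c(1, 0, 1, 0, 0, 0),
      bsCZ_1 = c(0, 1, 1, 0, 1, 0), bsCZ_2 = c(0, 1, 0, 0, 1, 0),
      gSP_1 = c(0, 0, 1, 1, 1, 0), gSP_2 = c(0, 0, 1, 0, 0, 0),
      gCZ_1 = c(0, 0, 1, 0, 0, 1), gCZ_2 = c(0, 0, 0, 0, 0, 1)
    ),
    c("A", "B", "C", "D", "E", "F")
  )
  meta <- make_metadata(
    names(tab)[-1],
    rep(c("SP", "CZ", "SP", "CZ"), each = 2),
    rep(c("bulk", "culturome"), each = 4),
    rep(1:2, 4)
  )
  cen <- overlap_census(tab, meta)
  got <- setNames(cen$n_shared, cen$comparison)
  expect_equal(got[["bulk_vs_culturome_SP"]], 2) # {C,D}
  expect_equal(got[["bulk_vs_culturome_CZ"]], 1) # {C}
  expect_equal(got[["SP_vs_CZ_bulk"]], 2) # {B,C}
  expect_equal(got[["SP_vs_CZ_culturome"]], 1) # {C}
  expect_equal(got[["core_all_groups"]], 1) # {C}
})

test_that("identical and disjoint groups give degenerate censuses", {
  tab <- make_table(
    list(
      bsSP_1 = c(1, 1, 0), bsCZ_1 = c(1, 1, 0),
      gSP_1 = c(1, 1, 0), gCZ_1 = c(1, 1, 0),
      bsSP_2 = c(1, 1, 0), bsCZ_2 = c(1, 1, 0),
      gSP_2 = c(1, 1, 0), gCZ_2 = c(1, 1, 0)
    ),
    c("A", "B", "C")
  )
  meta <- make_metadata(
    names(tab)[-1],
    rep(c("SP", "CZ", "SP", "CZ"), 2),
    rep(c("bulk", "bulk", "culturome", "culturome"), 2),
    rep(1:2, each = 4)
  )
  cen <- overlap_census(tab, meta)
  expect_true(all(cen$n_shared == 2))
})

test_that("a proportional culturome yields slope one with a tiny p", {
  counts <- c(512, 256, 128, 64, 32, 16, 8, 4, 2, 1)
  tab <- make_table(
    list(
      bsSP_1 = counts, bsSP_2 = counts,
      gSP_1 = counts, gSP_2 = counts
    ),
    sprintf("x%02d", 1:10)
  )
  meta <- make_metadata(
    names(tab)[-1], "SP", rep(c("bulk", "culturome"), each = 2), rep(1:2, 2)
  )
  fit <- suppressWarnings(abundance_relationship_test(tab, meta, "SP"))
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_lt(fit$p_value, 1e-6)
})

test_that("the abundance test needs at least 3 shared taxa", {
  tab <- make_table(
    list(bsSP_1 = c(1, 1, 0), bsSP_2 = c(1, 1, 0), gSP_1 = c(1, 1, 0), gSP_2 = c(1, 0, 1)),
    c("A", "B", "C")
  )
  meta <- make_metadata(
    names(tab)[-1], "SP", rep(c("bulk", "culturome"), each = 2), rep(1:2, 2)
  )
  expect_error(abundance_relationship_test(tab, meta, "SP"), "at least 3 taxa")
})

test_that("median-of-ratios size factors recover a doubled library", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
    dimnames = list(c("A", "B", "C"), c("s1", "s2"))
  )
  sf <- cdiv:::size_factors(m)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
})

test_that("the differential screen is quiet on null data and loud on signal", {
  set.seed(202)
  meta <- make_metadata(
    paste0("s", 1:8), rep(c("SP", "CZ"), each = 4), "bulk", rep(1:4, 2)
  )
  clean <- replicate(200, {
    m <- matrix(rpois(40 * 8, 50), nrow = 40,
      dimnames = list(sprintf("x%02d", 1:40), paste0("s", 1:8))
    )
    res <- differential_screen(cdiv:::counts_to_table(m), meta)
    sum(res$p_adjusted < 0.05) == 0
  })
  expect_gte(mean(clean), 0.95)

  # a strong true difference is found
  m <- matrix(rpois(40 * 8, 50), nrow = 40,
    dimnames = list(sprintf("x%02d", 1:40), paste0("s", 1:8))
  )
  m[1, 5:8] <- m[1, 5:8] * 20
  res <- differential_screen(cdiv:::counts_to_table(m), meta)
  expect_lt(res$p_adjusted[1], 0.05)
  expect_gt(abs(res$log2_fold_change[1]), 1)
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12))
})

test_that("Benjamini-Hochberg adjustment is the classic step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123) # single test unchanged
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})
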