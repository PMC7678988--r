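#' Shared-taxon divergence curve along an agglomeration ladder
#'
#' For one fraction (bulk or culturome), walks the ladder from phylotype
#' level towards a single cluster and, at every level, collapses the count
#' table, forms the SP and CZ presence sets, and records the percentage of
#' clusters shared between the two soil types,
#' \eqn{100 \cdot |SP \cap CZ| / |SP \cup CZ|} (the union is the only
#' symmetric denominator). `n_taxa` is the union size.
#'
#' @param ladder A `cdiv_ladder` over the table's taxa.
#' @param table Phylotype table (rarefied counts recommended).
#' @param metadata Sample metadata.
#' @param fraction `"bulk"` or `"culturome"`.
#' @param min_count,min_samples Presence criterion, see [presence_set()].
#' @return Tibble with `fraction`, `level`, `threshold`, `n_taxa`,
#'   `shared_pct`.
#' @export
divergence_curve <- function(ladder, table, metadata, fraction,
                             min_count = 1, min_samples = 1) {
  m <- as_count_matrix(table)
  check_metadata(metadata)
  if (!fraction %in% metadata$fraction) {
    abort(paste0("no samples with fraction '", fraction, "'"))
  }
  sp <- group_samples(metadata, "SP", fraction)
  cz <- group_samples(metadata, "CZ", fraction)
  sp <- intersect(sp, colnames(m))
  cz <- intersect(cz, colnames(m))
  if (!length(sp) || !length(cz)) {
    abort(paste0("both soil types must be present for fraction '", fraction, "'"))
  }
  missing_taxa <- setdiff(rownames(m), ladder$taxon_ids)
  if (length(missing_taxa)) abort("ladder does not cover all table taxa")

  msub <- m[, c(sp, cz), drop = FALSE]
  sp_idx <- seq_along(sp)
  cz_idx <- length(sp) + seq_along(cz)

  rows <- purrr::map_dfr(seq_along(ladder$thresholds), function(l) {
    cl <- ladder$membership[rownames(msub), l]
    collapsed <- rowsum(msub, group = cl, reorder = FALSE)
    det <- collapsed >= min_count
    in_sp <- rowSums(det[, sp_idx, drop = FALSE]) >= min_samples
    in_cz <- rowSums(det[, cz_idx, drop = FALSE]) >= min_samples
    n_union <- sum(in_sp | in_cz)
    tibble::tibble(
      level = l,
      threshold = ladder$thresholds[l],
      n_taxa = n_union,
      shared_pct = if (n_union == 0) NA_real_ else 100 * sum(in_sp & in_cz) / n_union
    )
  })
  dplyr::bind_cols(tibble::tibble(fraction = fraction), rows)
}

#' Linear fit of a divergence curve
#'
#' Ordinary least squares of the shared percentage on the merged-taxon
#' fraction \eqn{x = 1 - N_l / N_0}, restricted to levels that still retain
#' at least `min_taxa` clusters (the near-saturated tail of the curve is
#' uninformative about the divergence rate). Slopes are in percent shared
#' per unit merged fraction.
#'
#' @param curve Tibble from [divergence_curve()].
#' @param min_taxa Minimum cluster count for a level to enter the fit
#'   (default 50).
#' @return A `cdiv_regression` with `slope`, `intercept`, `slope_se`,
#'   `r_squared`, `p_value` (F test of zero slope), `n_points`.
#' @export
fit_divergence_regression <- function(curve, min_taxa = 50) {
  pts <- divergence_xy(curve, min_taxa)
  if (nrow(pts) < 3) {
    abort(paste0(
      "need at least 3 curve points with n_taxa >= ", min_taxa,
      " (got ", nrow(pts), ")"
    ))
  }
  fit <- lm(shared_pct ~ x, data = pts)
  new_cdiv_regression(
    fit,
    n_points = nrow(pts),
    x_definition = "1 - n_taxa / n_taxa_initial (fraction of taxa merged)"
  )
}

divergence_xy <- function(curve, min_taxa) {
  if (!all(c("n_taxa", "shared_pct") %in% names(curve))) {
    abort("`curve` must come from divergence_curve()")
  }
  n0 <- curve$n_taxa[1]
  pts <- dplyr::mutate(curve, x = 1 - .data$n_taxa / n0)
  dplyr::filter(pts, .data$n_taxa >= min_taxa, is.finite(.data$shared_pct))
}

new_cdiv_regression <- function(fit, n_points, x_definition) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(
      slope = unname(co["x", "Estimate"]),
      intercept = unname(co["(Intercept)", "Estimate"]),
      slope_se = unname(co["x", "Std. Error"]),
      r_squared = sm$r.squared,
      p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
        lower.tail = FALSE
      )),
      n_points = n_points,
      x_definition = x_definition,
      fit = fit
    ),
    class = "cdiv_regression"
  )
}

#' @export
print.cdiv_regression <- function(x, ...) {
  cat(sprintf(
    "linear fit: slope = %.4g (SE %.3g), intercept = %.4g, R2 = %.3f, p = %.3g, n = %d\n",
    x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value, x$n_points
  ))
  cat("x:", x$x_definition, "\n")
  invisible(x)
}

#' Tidy a linear fit
#'
#' @param x A `cdiv_regression`.
#' @param ... Unused.
#' @return One-row tibble of the fit summary.
#' @export
tidy.cdiv_regression <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
    r_squared = x$r_squared, p_value = x$p_value, n_points = x$n_points
  )
}

#' @rdname tidy.cdiv_regression
#' @export
glance.cdiv_regression <- function(x, ...) tidy(x, ...)

#' Compare divergence slopes between two curves
#'
#' Pools the eligible points of two divergence curves into one regression
#' with a fraction indicator and its interaction with x, and F-tests the
#' interaction coefficient — i.e. whether the two slopes differ.
#'
#' @param curve_a,curve_b Tibbles from [divergence_curve()] (or any tibbles
#'   with `n_taxa` and `shared_pct`).
#' @param min_taxa Eligibility cutoff as in [fit_divergence_regression()].
#' @return A `cdiv_slope_comparison` with `slope_a`, `slope_b`, `F_stat`,
#'   `df`, `p_value`. With zero residual variance the p-value is `NaN`
#'   (flagged `degenerate`).
#' @export
compare_slopes <- function(curve_a, curve_b, min_taxa = 50) {
  a <- divergence_xy(curve_a, min_taxa)
  b <- divergence_xy(curve_b, min_taxa)
  if (nrow(a) < 3 || nrow(b) < 3) {
    abort(paste0("both curves need at least 3 points with n_taxa >= ", min_taxa))
  }
  if (var(a$x) == 0 || var(b$x) == 0) abort("degenerate curve: zero variance in x")
  pooled <- dplyr::bind_rows(
    dplyr::mutate(a, which = "a"),
    dplyr::mutate(b, which = "b")
  )
  full <- lm(shared_pct ~ x * which, data = pooled)
  reduced <- lm(shared_pct ~ x + which, data = pooled)
  av <- anova(reduced, full)
  cf <- coef(full)
  slope_a <- unname(cf["x"])
  slope_b <- slope_a + unname(cf["x:whichb"])
  f_stat <- av$F[2]
  p <- av$`Pr(>F)`[2]
  # zero residual variance (e.g. two noiseless curves) leaves no error term
  rss <- sum(stats::residuals(full)^2)
  degenerate <- !is.finite(f_stat) ||
    rss < 1e-10 * (1 + sum(pooled$shared_pct^2))
  structure(
    list(
      slope_a = slope_a, slope_b = slope_b,
      F_stat = if (degenerate) NaN else f_stat,
      df = c(av$Df[2], av$Res.Df[2]),
      p_value = if (degenerate) NaN else p,
      degenerate = degenerate,
      n_points = c(nrow(a), nrow(b))
    ),
    class = "cdiv_slope_comparison"
  )
}

#' @export
print.cdiv_slope_comparison <- function(x, ...) {
  cat(sprintf(
    "slope comparison: %.4g vs %.4g, F = %.4g (df %d, %d), p = %.3g%s\n",
    x$slope_a, x$slope_b, x$F_stat, x$df[1], x$df[2], x$p_value,
    if (x$degenerate) " [degenerate: zero residual variance]" else ""
  ))
  invisible(x)
}

#' Tidy a slope comparison
#'
#' @param x A `cdiv_slope_comparison`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
tidy.cdiv_slope_comparison <- function(x, ...) {
  tibble::tibble(
    slope_a = x$slope_a, slope_b = x$slope_b, F_stat = x$F_stat,
    df1 = x$df[1], df2 = x$df[2], p_value = x$p_value
  )
}

#' Overlap census of presence sets
#'
#' Counts of taxa shared between bulk soil and culturome within each soil
#' type, between the two soil types within each fraction, and the core
#' present in all four groups.
#'
#' @param table Phylotype table.
#' @param metadata Sample metadata with all four (soil, fraction) groups.
#' @param min_count,min_samples Presence criterion, see [presence_set()].
#' @return Tibble with `comparison`, `n_shared`, `n_a`, `n_b`.
#' @export
overlap_census <- function(table, metadata, min_count = 1, min_samples = 1) {
  sets <- list(
    bulk_SP = presence_set(table, metadata, "SP", "bulk", min_count, min_samples),
    bulk_CZ = presence_set(table, metadata, "CZ", "bulk", min_count, min_samples),
    cult_SP = presence_set(table, metadata, "SP", "culturome", min_count, min_samples),
    cult_CZ = presence_set(table, metadata, "CZ", "culturome", min_count, min_samples)
  )
  pair <- function(name, a, b) {
    tibble::tibble(
      comparison = name,
      n_shared = length(intersect(sets[[a]], sets[[b]])),
      n_a = length(sets[[a]]),
      n_b = length(sets[[b]])
    )
  }
  core <- Reduce(intersect, sets)
  dplyr::bind_rows(
    pair("bulk_vs_culturome_SP", "bulk_SP", "cult_SP"),
    pair("bulk_vs_culturome_CZ", "bulk_CZ", "cult_CZ"),
    pair("SP_vs_CZ_bulk", "bulk_SP", "bulk_CZ"),
    pair("SP_vs_CZ_culturome", "cult_SP", "cult_CZ"),
    tibble::tibble(
      comparison = "core_all_groups", n_shared = length(core),
      n_a = NA_integer_, n_b = NA_integer_
    )
  )
}

#' Bulk-versus-culturome abundance relationship test
#'
#' Does a phylotype's abundance in the culturome track its abundance in the
#' bulk soil it was plated from? For one soil type, taxa present in both
#' fractions are collected; the per-taxon mean relative abundance in the
#' culturome is regressed on the bulk value on the log10 scale
#' (`log10(y + eps) ~ log10(x + eps)`), and the slope is F-tested against
#' zero. The pseudocount defaults to half the smallest positive relative
#' abundance in the dataset.
#'
#' @param table Phylotype table.
#' @param metadata Sample metadata.
#' @param soil_type `"SP"` or `"CZ"`.
#' @param pseudocount Positive pseudo relative abundance; `NULL` for the
#'   data-driven default.
#' @return A `cdiv_regression` (slope, SE, R2, F-test p, n taxa).
#' @export
abundance_relationship_test <- function(table, metadata, soil_type,
                                        pseudocount = NULL) {
  m <- as_count_matrix(table)
  check_metadata(metadata)
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  bulk <- intersect(group_samples(metadata, soil_type, "bulk"), colnames(m))
  cult <- intersect(group_samples(metadata, soil_type, "culturome"), colnames(m))
  if (!length(bulk) || !length(cult)) {
    abort(paste0("soil '", soil_type, "' needs both bulk and culturome samples"))
  }
  x <- rowMeans(rel[, bulk, drop = FALSE])
  y <- rowMeans(rel[, cult, drop = FALSE])
  both <- x > 0 & y > 0
  if (sum(both) < 3) {
    abort(paste0(
      "need at least 3 taxa present in both fractions (got ", sum(both), ")"
    ))
  }
  eps <- pseudocount %||% (min(rel[rel > 0]) / 2)
  dat <- tibble::tibble(
    lx = log10(x[both] + eps),
    shared_pct = log10(y[both] + eps) # response; reuse plumbing below
  )
  fit <- lm(shared_pct ~ lx, data = dat)
  # rename the coefficient for reporting
  res <- summary(fit)$coefficients
  structure(
    list(
      slope = unname(res["lx", "Estimate"]),
      intercept = unname(res["(Intercept)", "Estimate"]),
      slope_se = unname(res["lx", "Std. Error"]),
      r_squared = summary(fit)$r.squared,
      p_value = unname(pf(summary(fit)$fstatistic[1], summary(fit)$fstatistic[2],
        summary(fit)$fstatistic[3],
        lower.tail = FALSE
      )),
      n_points = sum(both),
      x_definition = "log10(mean bulk relative abundance + pseudocount)",
      pseudocount = eps,
      fit = fit
    ),
    class = "cdiv_regression"
  )
}

#' Full shared-taxon divergence analysis
#'
#' Convenience wrapper running the whole divergence pipeline: rarefy the
#' table, build the single-linkage ladder from the tree's cophenetic
#' distances, compute the bulk and culturome divergence curves, fit both
#' regressions and compare the slopes.
#'
#' @param table Phylotype table.
#' @param tree Phylogeny covering the table taxa.
#' @param metadata Sample metadata with all four (soil, fraction) groups.
#' @param levels Number of ladder levels (default 40).
#' @param min_taxa Regression eligibility cutoff (default 50).
#' @param seed Seed for the rarefaction step.
#' @return List with `curves` (tibble over both fractions), `fit_bulk`,
#'   `fit_culturome` and `comparison`.
#' @export
divergence_analysis <- function(table, tree, metadata, levels = 40,
                                min_taxa = 50, seed = NULL) {
  rar <- rarefy_table(table, seed = seed)
  coph <- cophenetic_matrix(tree)
  ladder <- single_linkage_ladder(coph, agglomeration_thresholds(coph, levels))
  bulk <- divergence_curve(ladder, rar, metadata, "bulk")
  cult <- divergence_curve(ladder, rar, metadata, "culturome")
  list(
    curves = dplyr::bind_rows(bulk, cult),
    fit_bulk = fit_divergence_regression(bulk, min_taxa),
    fit_culturome = fit_divergence_regression(cult, min_taxa),
    comparison = compare_slopes(bulk, cult, min_taxa)
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' The classic FDR step-up: sort p-values, multiply the i-th smallest by
#' n/i, then enforce monotonicity from the largest down and cap at 1.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  n <- length(p)
  if (n == 0) {
    return(numeric(0))
  }
  ord <- order(p)
  scaled <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(ord)]
}

#' Simplified differential-abundance screen
#'
#' A light-weight two-group screen preserving the pipeline position and FDR
#' semantics of a full negative-binomial differential-abundance analysis,
#' without its shrinkage machinery: counts are normalised by median-of-ratios
#' size factors (geometric-mean reference over taxa observed in every
#' sample; library-size factors with a warning if no such taxon exists), a
#' Welch t statistic is computed per taxon on log2(normalised count + 1),
#' and p-values are Benjamini-Hochberg adjusted.
#'
#' @param table Phylotype table.
#' @param metadata Sample metadata.
#' @param grouping Metadata column defining exactly two groups over the
#'   table's samples (default `"soil_type"`).
#' @return Tibble with `taxon_id`, `base_mean`, `log2_fold_change`,
#'   `statistic`, `p_value`, `p_adjusted`, ordered as the input table.
#'   `log2_fold_change` is the difference of group means of
#'   log2(normalised count + 1), second group minus first.
#' @export
differential_screen <- function(table, metadata, grouping = "soil_type") {
  m <- as_count_matrix(table)
  check_metadata(metadata, colnames(m))
  if (!grouping %in% names(metadata)) {
    abort(paste0("metadata lacks grouping column '", grouping, "'"))
  }
  g <- metadata[[grouping]][match(colnames(m), metadata$sample_id)]
  lev <- sort(unique(g))
  if (length(lev) != 2) abort("`grouping` must define exactly two groups")
  if (any(table(g) < 2)) abort("each group needs at least 2 samples")

  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  lg <- log2(norm + 1)
  ia <- which(g == lev[1])
  ib <- which(g == lev[2])

  welch <- function(v) {
    xa <- v[ia]
    xb <- v[ib]
    dm <- mean(xb) - mean(xa)
    se2 <- var(xa) / length(xa) + var(xb) / length(xb)
    if (se2 == 0) {
      return(c(stat = if (dm == 0) 0 else sign(dm) * Inf, p = if (dm == 0) 1 else 0))
    }
    tt <- dm / sqrt(se2)
    df <- se2^2 / ((var(xa) / length(xa))^2 / (length(xa) - 1) +
      (var(xb) / length(xb))^2 / (length(xb) - 1))
    c(stat = tt, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
  }
  stats_mat <- t(apply(lg, 1, welch))
  p <- stats_mat[, "p"]
  tibble::tibble(
    taxon_id = rownames(m),
    base_mean = rowMeans(norm),
    log2_fold_change = rowMeans(lg[, ib, drop = FALSE]) - rowMeans(lg[, ia, drop = FALSE]),
    statistic = stats_mat[, "stat"],
    p_value = p,
    p_adjusted = bh_adjust(p)
  )
}

# median-of-ratios size factors; library-size fallback when no taxon is
# observed in every sample
size_factors <- function(m) {
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    warn("no taxon observed in every sample; using library-size factors")
    libs <- colSums(m)
    return(libs / exp(mean(log(libs))))
  }
  ref <- exp(rowMeans(log(m[allpos, , drop = FALSE])))
  apply(m[allpos, , drop = FALSE], 2, function(col) median(col / ref))
}
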