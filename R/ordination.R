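#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: eigendecomposition of the
#' double-centred \eqn{-\tfrac12 D^2} matrix (via [ape::pcoa()]). Axes are
#' ordered by decreasing eigenvalue; negative eigenvalues are reported but
#' never used for coordinates. No eigenvalue correction is applied unless
#' `correction = "cailliez"`.
#'
#' @param D A `dist` or square labelled distance matrix (n >= 3).
#' @param n_axes Number of axes to retain (clipped to the positive axes
#'   available, with a warning).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return A `cdiv_pcoa` object: `coordinates` (tibble with `sample_id` and
#'   `Axis.k` columns), `eigenvalues`, `proportion_explained`.
#' @export
pcoa_ordination <- function(D, n_axes = 2, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  m <- check_distance_matrix(D)
  n <- nrow(m)
  if (n < 3) abort("PCoA needs at least 3 samples")
  ids <- rownames(m)

  if (all(m == 0)) {
    coords <- matrix(0, n, n_axes, dimnames = list(ids, paste0("Axis.", seq_len(n_axes))))
    return(new_cdiv_pcoa(coords, rep(0, n - 1), rep(0, n - 1), ids))
  }

  fit <- ape::pcoa(as.dist(m), correction = if (correction == "cailliez") "cailliez" else "none")
  eig <- fit$values$Eigenvalues
  rel <- if (!is.null(fit$values$Rel_corr_eig)) fit$values$Rel_corr_eig else fit$values$Relative_eig
  vecs <- fit$vectors
  n_pos <- ncol(vecs)
  if (n_axes > n_pos) {
    warn(paste0("n_axes clipped from ", n_axes, " to ", n_pos, " positive axes"))
    n_axes <- n_pos
  }
  coords <- vecs[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("Axis.", seq_len(n_axes))
  rownames(coords) <- ids
  new_cdiv_pcoa(coords, eig, rel, ids)
}

new_cdiv_pcoa <- function(coords, eigenvalues, proportion_explained, ids) {
  structure(
    list(
      coordinates = dplyr::bind_cols(
        tibble::tibble(sample_id = ids),
        tibble::as_tibble(coords)
      ),
      eigenvalues = eigenvalues,
      proportion_explained = proportion_explained
    ),
    class = "cdiv_pcoa"
  )
}

#' @export
print.cdiv_pcoa <- function(x, ...) {
  k <- sum(grepl("^Axis", names(x$coordinates)))
  cat("PCoA ordination:", nrow(x$coordinates), "samples,", k, "axes retained\n")
  pe <- round(100 * x$proportion_explained[seq_len(min(k, length(x$proportion_explained)))], 1)
  cat("proportion explained (%):", paste(pe, collapse = ", "), "\n")
  invisible(x)
}

#' PERMANOVA from a distance matrix
#'
#' Permutational multivariate analysis of variance: partitions the total sum
#' of squared distances (\eqn{SS_T = \sum_{i<j} d_{ij}^2 / n}) into between-
#' and within-group components, forms the pseudo-F
#' \eqn{(SS_B/(a-1)) / (SS_W/(n-a))}, and assesses it by random relabelling
#' of samples. The p-value uses the add-one correction,
#' \eqn{p = (\#\{F^\pi \ge F\} + 1)/(B + 1)}, so it is never exactly zero.
#'
#' @param D A `dist` or square labelled distance matrix.
#' @param groups Group labels: either a vector in the order of the matrix
#'   ids, or a named vector/factor keyed by sample id.
#' @param n_permutations Number of random label permutations (default 999).
#'   Alternatively a matrix whose rows are explicit index permutations
#'   (e.g. the complete enumeration for small n); the p-value is then the
#'   exact fraction of enumerated F values at or above the observed one.
#' @param seed Integer seed for the permutations.
#' @return A `cdiv_permanova` object with `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, and degrees of freedom; see [tidy.cdiv_permanova()].
#' @export
permanova <- function(D, groups, n_permutations = 999, seed = NULL) {
  m <- check_distance_matrix(D)
  n <- nrow(m)
  ids <- rownames(m)
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(ids, names(groups))
    if (length(missing_ids)) abort("`groups` lacks labels for some samples")
    groups <- groups[ids]
  }
  groups <- as.factor(as.vector(groups))
  if (length(groups) != n) abort("`groups` must label every sample")
  if (nlevels(droplevels(groups)) < 2) abort("PERMANOVA needs at least 2 groups")
  if (any(table(groups) < 2)) abort("every group needs at least 2 samples")

  m2 <- m^2
  f_stat <- permanova_F(m2, as.integer(groups), nlevels(groups))
  # NaN arises only for constant D (0/0); Inf (complete separation) is valid
  if (is.nan(f_stat$F)) {
    return(new_cdiv_permanova(NaN, f_stat$R2, NA_real_, 0L, f_stat$df, groups))
  }

  if (is.matrix(n_permutations)) {
    perms <- n_permutations
    if (ncol(perms) != n) abort("permutation matrix must have one column per sample")
    f_perm <- apply(perms, 1, function(idx) {
      permanova_F(m2, as.integer(groups)[idx], nlevels(groups))$F
    })
    # exhaustive semantics: the supplied set defines the null distribution
    p <- mean(f_perm >= f_stat$F - 1e-12)
    b <- nrow(perms)
  } else {
    b <- as.integer(n_permutations)
    f_perm <- with_seed_maybe(seed, vapply(seq_len(b), function(i) {
      permanova_F(m2, sample(as.integer(groups)), nlevels(groups))$F
    }, double(1)))
    p <- (sum(f_perm >= f_stat$F - 1e-12) + 1) / (b + 1)
  }
  new_cdiv_permanova(f_stat$F, f_stat$R2, p, b, f_stat$df, groups)
}

# pseudo-F from the squared-distance matrix and integer group codes
permanova_F <- function(m2, g, a) {
  n <- nrow(m2)
  ss_total <- sum(m2[lower.tri(m2)]) / n
  ss_within <- 0
  for (k in seq_len(a)) {
    idx <- which(g == k)
    if (length(idx) > 1) {
      sub <- m2[idx, idx]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  df_b <- a - 1
  df_w <- n - a
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(F = f, R2 = ss_between / ss_total, df = c(df_b, df_w))
}

new_cdiv_permanova <- function(F, R2, p, b, df, groups) {
  structure(
    list(
      pseudo_F = F, R2 = R2, p_value = p, n_permutations = b,
      df = df, group_sizes = as.integer(table(groups))
    ),
    class = "cdiv_permanova"
  )
}

#' @export
print.cdiv_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), R2 = %.3f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$df[1], x$df[2], x$R2, x$p_value, x$n_permutations
  ))
  invisible(x)
}

#' Distance between group centroids
#'
#' Distance between the centres of mass of two sample groups, computed
#' directly from the pairwise distance matrix through the squared-distance
#' identity
#' \deqn{\delta^2 = \frac{1}{n_a n_b}\sum_{i \in a, j \in b} d_{ij}^2
#'   - \frac{1}{n_a^2}\sum_{i < i' \in a} d_{ii'}^2
#'   - \frac{1}{n_b^2}\sum_{j < j' \in b} d_{jj'}^2.}
#' For a non-Euclidean matrix \eqn{\delta^2} can be negative; the value is
#' then reported as 0 with `non_euclidean = TRUE`.
#'
#' @param D A `dist` or square labelled distance matrix.
#' @param group_a,group_b Disjoint, non-empty character vectors of ids.
#' @return A `cdiv_centroid` object with `value`, `group_sizes`,
#'   `non_euclidean`.
#' @export
centroid_distance <- function(D, group_a, group_b) {
  m <- check_distance_matrix(D)
  ids <- rownames(m)
  if (length(intersect(group_a, group_b))) abort("groups must be disjoint")
  if (!length(group_a) || !length(group_b)) abort("groups must be non-empty")
  unknown <- setdiff(c(group_a, group_b), ids)
  if (length(unknown)) {
    abort(paste0("ids absent from D: ", paste(unknown, collapse = ", ")))
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  m2 <- m^2
  cross <- sum(m2[group_a, group_b, drop = FALSE]) / (n_a * n_b)
  within_a <- sum(m2[group_a, group_a, drop = FALSE]) / 2 / n_a^2
  within_b <- sum(m2[group_b, group_b, drop = FALSE]) / 2 / n_b^2
  v2 <- cross - within_a - within_b
  structure(
    list(
      value = if (v2 < 0) 0 else sqrt(v2),
      group_sizes = c(n_a, n_b),
      non_euclidean = v2 < -1e-12
    ),
    class = "cdiv_centroid"
  )
}

#' @export
print.cdiv_centroid <- function(x, ...) {
  cat(sprintf(
    "centroid distance = %.6g (groups of %d and %d)%s\n",
    x$value, x$group_sizes[1], x$group_sizes[2],
    if (x$non_euclidean) " [non-Euclidean input, clamped to 0]" else ""
  ))
  invisible(x)
}
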