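#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d(x,y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, computed with
#' [vegan::vegdist()]. Bounded in \[0, 1\].
#'
#' @param table Phylotype table.
#' @return A `dist` of pairwise sample dissimilarities.
#' @export
bray_curtis_matrix <- function(table) {
  m <- as_count_matrix(table)
  if (any(colSums(m) == 0)) {
    abort("Bray-Curtis is undefined for all-zero samples")
  }
  vegan::vegdist(t(m), method = "bray")
}

#' UniFrac distances between samples
#'
#' Phylogenetic beta diversity from branch lengths shared versus unique
#' between two communities. Unweighted UniFrac is the fraction of observed
#' branch length unique to one community's tip set; weighted UniFrac uses
#' subtree relative abundances, \eqn{\sum_k b_k |p_k - q_k| / \sum_k b_k
#' (p_k + q_k)} when `normalized` (bounded \[0, 1\]), or the unnormalised
#' numerator otherwise.
#'
#' @param table Phylotype table; taxa must all be tips of `tree`.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param weighted Use relative abundances instead of presence.
#' @param normalized For weighted UniFrac, divide by
#'   \eqn{\sum_k b_k (p_k + q_k)} so distances are bounded by 1.
#' @return A `dist` of pairwise sample distances.
#' @export
unifrac_matrix <- function(table, tree, weighted = FALSE, normalized = TRUE) {
  m <- as_count_matrix(table)
  validate_phylogeny(tree)
  missing_tips <- setdiff(rownames(m), tree$tip.label)
  if (length(missing_tips)) {
    abort(paste0(
      "table taxa absent from tree: ", paste(head(missing_tips, 5), collapse = ", ")
    ))
  }
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(paste0(
      "UniFrac is undefined for all-zero sample(s): ",
      paste(colnames(m)[totals == 0], collapse = ", ")
    ))
  }

  sub <- edge_subtree_sums(tree, m) # edges x samples, subtree read counts
  blen <- tree$edge.length
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  if (weighted) {
    p <- sweep(sub, 2, totals, "/")
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        num <- sum(blen * abs(p[, i] - p[, j]))
        d <- if (normalized) {
          den <- sum(blen * (p[, i] + p[, j]))
          if (den == 0) 0 else num / den
        } else {
          num
        }
        out[i, j] <- out[j, i] <- d
      }
    }
  } else {
    pres <- sub > 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        either <- pres[, i] | pres[, j]
        uniq <- xor(pres[, i], pres[, j])
        den <- sum(blen[either])
        out[i, j] <- out[j, i] <- if (den == 0) 0 else sum(blen[uniq]) / den
      }
    }
  }
  as.dist(out)
}

# per-edge subtree read sums: rows follow tree$edge order
edge_subtree_sums <- function(tree, m) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nsamp <- ncol(m)
  node_sums <- matrix(0, ntip + nnode, nsamp)
  node_sums[seq_len(ntip), ] <- m[tree$tip.label, , drop = FALSE]
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1]
    child <- tr$edge[k, 2]
    node_sums[parent, ] <- node_sums[parent, ] + node_sums[child, ]
  }
  # report in the original tree's edge order (child node indexes are stable)
  node_sums[tree$edge[, 2], , drop = FALSE]
}

#' Between-community mean pairwise phylogenetic distance
#'
#' MPD between two samples: the mean cophenetic (tip-to-tip path) distance
#' over all cross-community taxon pairs. Unweighted uses presence;
#' weighted uses relative abundances, \eqn{\sum_{ij} p_i q_j d_{ij}}. Note
#' MPD-between is not a metric: a community compared with itself returns its
#' within-community mean pairwise distance, not 0.
#'
#' @param table Phylotype table.
#' @param tree Rooted `phylo` tree covering the table taxa.
#' @param abundance_weighted Weight tip pairs by relative abundances.
#' @return A `dist` of pairwise sample values (self-comparisons omitted).
#' @export
mpd_between_matrix <- function(table, tree, abundance_weighted = FALSE) {
  m <- as_count_matrix(table)
  missing_tips <- setdiff(rownames(m), tree$tip.label)
  if (length(missing_tips)) {
    abort(paste0(
      "table taxa absent from tree: ", paste(head(missing_tips, 5), collapse = ", ")
    ))
  }
  if (any(colSums(m) == 0)) abort("MPD is undefined for empty communities")
  dmat <- cophenetic_matrix(tree)
  dmat <- dmat[rownames(m), rownames(m)]
  w <- if (abundance_weighted) {
    sweep(m, 2, colSums(m), "/")
  } else {
    ind <- (m > 0) * 1
    sweep(ind, 2, colSums(ind), "/")
  }
  out <- t(w) %*% dmat %*% w
  dimnames(out) <- list(colnames(m), colnames(m))
  as.dist(out)
}

#' Cophenetic (tip-to-tip) distances of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips,
#' via [ape::cophenetic.phylo()].
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @return Square labelled matrix of taxon-taxon distances.
#' @export
cophenetic_matrix <- function(tree) {
  validate_phylogeny(tree)
  stats::cophenetic(tree)
}

#' Distance matrix as a tidy tibble
#'
#' @param d A `dist` or square labelled matrix.
#' @return Tibble with `id_a`, `id_b`, `distance`, one row per unordered pair.
#' @export
dist_tibble <- function(d) {
  m <- dist_to_matrix(d)
  ids <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    id_a = ids[idx[, 1]],
    id_b = ids[idx[, 2]],
    distance = m[idx]
  )
}
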