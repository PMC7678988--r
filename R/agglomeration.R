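#' Default agglomeration thresholds
#'
#' A ladder of cophenetic-distance thresholds for [single_linkage_ladder()].
#' `"quantile"` (default) places levels on evenly spaced quantiles of the
#' single-linkage merge heights, so the cluster count moves at every step
#' and decays steadily from one level to the next; `"linear"` spaces levels
#' evenly over the distance range. Level 1 is always threshold 0 (every
#' taxon its own cluster) and the last level reaches a single cluster.
#'
#' @param coph Taxon-taxon cophenetic distance matrix (or `dist`).
#' @param levels Total number of ladder levels (default 40).
#' @param ladder `"quantile"` or `"linear"`.
#' @return Increasing numeric vector of thresholds, length `levels`.
#' @export
agglomeration_thresholds <- function(coph, levels = 40, ladder = c("quantile", "linear")) {
  ladder <- match.arg(ladder)
  m <- check_distance_matrix(coph, "coph")
  if (levels < 2) abort("`levels` must be at least 2")
  hc <- hclust(as.dist(m), method = "single")
  probs <- seq_len(levels - 1) / (levels - 1)
  ts <- if (ladder == "quantile") {
    quantile(hc$height, probs, names = FALSE)
  } else {
    max(hc$height) * probs
  }
  unique_increasing(c(0, ts))
}

# enforce strictly increasing thresholds (collapse numeric ties)
unique_increasing <- function(x) {
  x[c(TRUE, diff(x) > 0)]
}

#' Single-linkage agglomeration ladder
#'
#' Nested partitions of taxa over increasing cophenetic-distance thresholds.
#' At threshold t, clusters are the connected components of the graph with
#' edges between taxa at distance <= t — equivalently a single-linkage
#' dendrogram cut at height t. Cluster ids are the lexicographically
#' smallest member taxon id, making partitions deterministic.
#'
#' @param coph Taxon-taxon cophenetic distance matrix (or `dist`).
#' @param thresholds Increasing numeric thresholds (see
#'   [agglomeration_thresholds()]).
#' @return A `cdiv_ladder` object; see [ladder_partition()] and
#'   [tidy.cdiv_ladder()].
#' @export
single_linkage_ladder <- function(coph, thresholds) {
  m <- check_distance_matrix(coph, "coph")
  if (is.unsorted(thresholds, strictly = FALSE)) {
    abort("`thresholds` must be sorted ascending")
  }
  taxa <- rownames(m)
  n <- length(taxa)
  hc <- hclust(as.dist(m), method = "single")
  membership <- vapply(thresholds, function(t) {
    if (t < min(hc$height)) seq_len(n) else cutree(hc, h = t)
  }, integer(n))
  if (is.null(dim(membership))) membership <- matrix(membership, nrow = n)
  rownames(membership) <- taxa

  cluster_ids <- lapply(seq_along(thresholds), function(l) {
    vapply(split(taxa, membership[, l]), min, character(1))
  })
  structure(
    list(
      thresholds = as.numeric(thresholds),
      membership = membership,
      cluster_ids = cluster_ids,
      taxon_ids = taxa,
      n_clusters = vapply(cluster_ids, length, integer(1))
    ),
    class = "cdiv_ladder"
  )
}

#' Partition at one ladder level
#'
#' @param ladder A `cdiv_ladder`.
#' @param level Level index (1-based).
#' @return Named character vector mapping taxon id to cluster id.
#' @export
ladder_partition <- function(ladder, level) {
  if (level < 1 || level > length(ladder$thresholds)) abort("no such ladder level")
  codes <- ladder$membership[, level]
  setNames(ladder$cluster_ids[[level]][as.character(codes)], ladder$taxon_ids)
}

#' @export
print.cdiv_ladder <- function(x, ...) {
  cat(
    "single-linkage ladder:", length(x$taxon_ids), "taxa,",
    length(x$thresholds), "levels,", "clusters",
    x$n_clusters[1], "->", x$n_clusters[length(x$n_clusters)], "\n"
  )
  invisible(x)
}

#' Tidy an agglomeration ladder
#'
#' @param x A `cdiv_ladder`.
#' @param ... Unused.
#' @return Tibble with `level`, `threshold`, `n_clusters`.
#' @export
tidy.cdiv_ladder <- function(x, ...) {
  tibble::tibble(
    level = seq_along(x$thresholds),
    threshold = x$thresholds,
    n_clusters = x$n_clusters
  )
}

#' Collapse a count table over a partition
#'
#' Sums member counts within each cluster; per-sample totals are conserved
#' exactly.
#'
#' @param table Phylotype table.
#' @param partition Named character vector taxon id -> cluster id, covering
#'   every table taxon (see [ladder_partition()]).
#' @param level Optional label recording the agglomeration level.
#' @return A `cdiv_collapsed` list: `table` (collapsed phylotype table),
#'   `level`, `member_map` (cluster id -> member taxon ids).
#' @export
collapse_table <- function(table, partition, level = NULL) {
  m <- as_count_matrix(table)
  missing_taxa <- setdiff(rownames(m), names(partition))
  if (length(missing_taxa)) {
    abort(paste0(
      "partition misses taxa: ", paste(head(missing_taxa, 5), collapse = ", ")
    ))
  }
  cl <- as.character(partition[rownames(m)])
  collapsed <- rowsum(m, group = cl, reorder = TRUE)
  structure(
    list(
      table = counts_to_table(collapsed),
      level = level,
      member_map = split(rownames(m), cl)
    ),
    class = "cdiv_collapsed"
  )
}

#' @export
print.cdiv_collapsed <- function(x, ...) {
  cat(
    "collapsed table:", nrow(x$table), "clusters",
    if (!is.null(x$level)) paste0("(level ", format(x$level), ")"), "\n"
  )
  invisible(x)
}

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Collapse a count table at a taxonomic rank
#'
#' Taxa whose lineage prefixes agree through `rank` (and are assigned at
#' that rank) merge into one cluster; taxa unassigned at `rank` stay
#' singletons.
#'
#' @param table Phylotype table.
#' @param taxonomy Taxonomy tibble (`taxon_id` + rank columns).
#' @param rank One of phylum, class, order, family, genus, species.
#' @return A `cdiv_collapsed`, as for [collapse_table()].
#' @export
collapse_by_rank <- function(table, taxonomy, rank) {
  if (!rank %in% TAXONOMY_RANKS) {
    abort(paste0("unknown rank: ", rank))
  }
  m <- as_count_matrix(table)
  missing_taxa <- setdiff(rownames(m), taxonomy$taxon_id)
  if (length(missing_taxa)) {
    abort(paste0(
      "taxonomy misses taxa: ", paste(head(missing_taxa, 5), collapse = ", ")
    ))
  }
  ranks_used <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
  ranks_used <- intersect(ranks_used, names(taxonomy))
  if (!rank %in% ranks_used) abort(paste0("taxonomy lacks a `", rank, "` column"))
  tax <- taxonomy[match(rownames(m), taxonomy$taxon_id), , drop = FALSE]
  prefix <- do.call(paste, c(lapply(ranks_used, function(r) tax[[r]]), sep = ";"))
  assigned <- !is.na(tax[[rank]]) & tax[[rank]] != ""
  key <- ifelse(assigned, prefix, paste0("__singleton__", rownames(m)))
  # cluster id: smallest member taxon id within each lineage group
  cl <- stats::ave(rownames(m), key, FUN = min)
  collapse_table(table, setNames(cl, rownames(m)), level = rank)
}

#' Presence set of a sample group
#'
#' Taxon (or cluster) ids detected in a (soil type, fraction) group: count
#' >= `min_count` in at least `min_samples` of the group's samples.
#' Applied to a rarefied table the defaults (1 read, 1 sample) give the
#' presence criterion used by the divergence curves.
#'
#' @param table Phylotype table (possibly collapsed).
#' @param metadata Sample metadata.
#' @param soil_type `"SP"` or `"CZ"`.
#' @param fraction `"bulk"` or `"culturome"`.
#' @param min_count Minimum count for detection in one sample (default 1).
#' @param min_samples Minimum number of detecting samples (default 1).
#' @return Character vector of ids.
#' @export
presence_set <- function(table, metadata, soil_type, fraction,
                         min_count = 1, min_samples = 1) {
  m <- as_count_matrix(table)
  check_metadata(metadata)
  samples <- group_samples(metadata, soil_type, fraction)
  samples <- intersect(samples, colnames(m))
  if (!length(samples)) {
    abort(paste0("no samples for group (", soil_type, ", ", fraction, ")"))
  }
  hits <- rowSums(m[, samples, drop = FALSE] >= min_count)
  rownames(m)[hits >= min_samples]
}
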