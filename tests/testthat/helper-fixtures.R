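# shared fixture builders; everything is generated in code

# wide phylotype table from a named list of sample count vectors
make_table <- function(counts, taxa) {
  dplyr::bind_cols(
    tibble::tibble(taxon_id = taxa),
    tibble::as_tibble(lapply(counts, as.numeric))
  )
}

# balanced 2-soil x 2-fraction metadata for n replicates per group
make_metadata <- function(sample_ids, soil_type, fraction,
                          replicate = NULL) {
  tibble::tibble(
    sample_id = sample_ids,
    soil_type = soil_type,
    fraction = fraction,
    replicate = replicate %||% seq_along(sample_ids)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the worked 4-tip tree used across the beta-diversity examples
balanced_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# random rooted tree with uniform branch lengths and labelled tips
random_tree <- function(n, seed = NULL) {
  cdiv:::with_seed_maybe(seed, {
    tr <- ape::rtree(n)
    tr$tip.label <- sprintf("t%03d", seq_len(n))
    tr
  })
}

# random count table over a tree's tips
random_table <- function(tree, n_samples, max_count = 20) {
  n <- length(tree$tip.label)
  m <- matrix(
    sample(0:max_count, n * n_samples, replace = TRUE),
    nrow = n,
    dimnames = list(tree$tip.label, paste0("s", seq_len(n_samples)))
  )
  # every sample must observe something
  for (j in seq_len(n_samples)) if (sum(m[, j]) == 0) m[1, j] <- 1
  cdiv:::counts_to_table(m)
}

# brute-force single-linkage partition: connected components of the
# threshold graph, found by union-find over all pairwise edges
brute_components <- function(d, t) {
  n <- nrow(d)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] <= t) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# all permutations of seq_len(n) (n small)
all_perms <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out <- rbind(out, block)
  }
  out
}

# same partition up to label renaming
same_partition <- function(a, b) {
  identical(
    as.integer(match(a, unique(a))),
    as.integer(match(b, unique(b)))
  )
}
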