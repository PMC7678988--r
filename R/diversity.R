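#' Rarefy a phylotype table to even depth
#'
#' Subsamples every sample without replacement (multivariate hypergeometric,
#' via [vegan::rrarefy()]) to a common number of reads, by default the
#' smallest sample total — the usual normalisation before diversity
#' comparisons across unevenly sequenced samples.
#'
#' @param table Phylotype table (`taxon_id` + sample columns).
#' @param depth Target reads per sample; default is the minimum sample total.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A rarefied phylotype table; every sample column sums to `depth`.
#' @export
rarefy_table <- function(table, depth = NULL, seed = NULL) {
  m <- as_count_matrix(table)
  totals <- colSums(m)
  depth <- depth %||% min(totals)
  low <- totals < depth
  if (any(low)) {
    abort(paste0(
      "depth ", depth, " exceeds the total of sample(s): ",
      paste(colnames(m)[low], collapse = ", ")
    ))
  }
  out <- with_seed_maybe(seed, t(quiet_rrarefy(t(m), depth)))
  dimnames(out) <- dimnames(m)
  counts_to_table(out)
}

#' Rarefaction curves
#'
#' Mean observed richness per sample over repeated random subsamples at a
#' grid of depths. Depths exceeding a sample's total are dropped for that
#' sample (the curve is truncated at the sample total).
#'
#' @param table Phylotype table.
#' @param depths Integer vector of subsampling depths.
#' @param reps Number of random subsamples per depth (default 10).
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `depth`, `mean_richness`.
#' @export
rarefaction_curve <- function(table, depths, reps = 10, seed = NULL) {
  m <- as_count_matrix(table)
  if (reps < 1) abort("`reps` must be at least 1")
  depths <- sort(unique(as.integer(depths)))
  if (any(depths < 1)) abort("`depths` must be positive")
  totals <- colSums(m)
  with_seed_maybe(seed, {
    purrr::map_dfr(colnames(m), function(s) {
      x <- m[, s]
      ds <- depths[depths <= totals[s]]
      if (!length(ds)) {
        return(tibble::tibble(
          sample_id = character(), depth = integer(), mean_richness = double()
        ))
      }
      rich <- vapply(ds, function(d) {
        mean(vapply(seq_len(reps), function(r) {
          sum(subsample_counts(x, d) > 0)
        }, double(1)))
      }, double(1))
      tibble::tibble(sample_id = s, depth = ds, mean_richness = rich)
    })
  })
}

# without-replacement subsample of a single count vector
subsample_counts <- function(x, depth) {
  drop(quiet_rrarefy(matrix(x, nrow = 1), depth))
}

# vegan::rrarefy warns whenever the smallest positive count exceeds 1,
# which is routine for amplicon tables; silence that advisory only
quiet_rrarefy <- function(m, depth) {
  withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Alpha diversity indices
#'
#' Observed richness, Shannon entropy (natural log), Pielou evenness and
#' inverse Simpson per sample. Indices other than richness are `NA` for
#' all-zero samples; Pielou is `NA` when richness is 1 (log 1 = 0).
#'
#' @param table Phylotype table.
#' @return Tibble with `sample_id`, `richness`, `shannon`,
#'   `pielou_evenness`, `inv_simpson`.
#' @export
alpha_diversity <- function(table) {
  m <- as_count_matrix(table)
  purrr::map_dfr(colnames(m), function(s) {
    x <- m[, s]
    total <- sum(x)
    rich <- sum(x > 0)
    if (total == 0) {
      return(tibble::tibble(
        sample_id = s, richness = 0L, shannon = NA_real_,
        pielou_evenness = NA_real_, inv_simpson = NA_real_
      ))
    }
    p <- x[x > 0] / total
    shannon <- -sum(p * log(p))
    tibble::tibble(
      sample_id = s,
      richness = as.integer(rich),
      shannon = shannon,
      pielou_evenness = if (rich >= 2) shannon / log(rich) else NA_real_,
      inv_simpson = 1 / sum(p^2)
    )
  })
}
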