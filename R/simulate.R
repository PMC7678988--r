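#' Simulation configuration
#'
#' Parameters of the paired bulk/culturome community generator. The
#' defaults mirror the study design the package targets: four groups
#' (2 soils x 2 fractions) of 6 replicates, bulk communities of several
#' hundred phylotypes sequenced to ~20k reads, culturomes holding roughly a
#' quarter of the taxa at ~30k reads, soil differentiation among close
#' relatives in bulk soil (`soil_effect_depth = 0.1`) but at the level of
#' whole deep clades in the culturome (`culturability_depth = 0.6`), and
#' culturome abundances decoupled from bulk abundances.
#'
#' Depths are fractions of tree height: soil differentiation at depth q is
#' generated on clades cut (by the package's single-linkage machinery) at
#' nested scales spanning (0, q], so differences exist at every phylogenetic
#' scale up to q. Bulk and culturome run the identical clade-level process
#' at their respective depths; the culturome additionally loses members of
#' broad culturable clades to soil-idiosyncratic establishment failure,
#' which vanishes when the culturable clades are narrow.
#'
#' @param n_taxa Number of phylotypes (>= 10).
#' @param n_samples_per_group Replicates per (soil, fraction) group.
#' @param bulk_depth,culturome_depth Reads per sample (>= 100).
#' @param soil_effect_depth Phylogenetic depth (fraction of tree height) of
#'   soil differentiation in bulk soil.
#' @param culturability_depth Depth of the culturable clades and of soil
#'   differentiation in the culturome.
#' @param culturable_clade_fraction Target fraction of taxa contained in
#'   whole culturable clades.
#' @param lognormal_sigma Log-scale SD of base abundances and of culturome
#'   growth potentials.
#' @param amplification_sigma Log-scale SD of per-replicate culturome
#'   growth noise (plate-to-plate variation).
#' @param soil_effect_sigma Total log-scale SD of clade-level soil
#'   abundance shifts (split across scales).
#' @param clade_knockout_prob Probability that a clade at the finest scale
#'   is absent from one soil; halves with each coarser scale.
#' @param establishment_failure Probability that a member of a broad
#'   culturable clade fails to establish on the plates of one soil
#'   (within-clade competition for the medium, idiosyncratic per soil
#'   inoculum); scaled by `max(0, 1 - 3/clade_size)`, so members of narrow
#'   culturable clades (few competitors) always establish.
#' @param n_scales Number of nested scales carrying soil differentiation.
#' @param bulk_coupling In \[0, 1\]: 0 (default) draws culturome abundances
#'   from fresh growth potentials (no bulk-culturome relationship); 1 makes
#'   expected culturome abundances proportional to bulk abundances.
#' @param seed Integer seed; a dataset is fully reproducible from its
#'   config.
#' @return A validated `cdiv_sim_config` list.
#' @export
simulation_config <- function(n_taxa = 600,
                              n_samples_per_group = 6,
                              bulk_depth = 20000,
                              culturome_depth = 30000,
                              soil_effect_depth = 0.1,
                              culturability_depth = 0.6,
                              culturable_clade_fraction = 0.25,
                              lognormal_sigma = 1.5,
                              amplification_sigma = 2.0,
                              soil_effect_sigma = 1.0,
                              clade_knockout_prob = 0.06,
                              establishment_failure = 0.45,
                              n_scales = 4,
                              bulk_coupling = 0,
                              seed = 1) {
  cfg <- list(
    n_taxa = as.integer(n_taxa),
    n_samples_per_group = as.integer(n_samples_per_group),
    bulk_depth = as.integer(bulk_depth),
    culturome_depth = as.integer(culturome_depth),
    soil_effect_depth = soil_effect_depth,
    culturability_depth = culturability_depth,
    culturable_clade_fraction = culturable_clade_fraction,
    lognormal_sigma = lognormal_sigma,
    amplification_sigma = amplification_sigma,
    soil_effect_sigma = soil_effect_sigma,
    clade_knockout_prob = clade_knockout_prob,
    establishment_failure = establishment_failure,
    n_scales = as.integer(n_scales),
    bulk_coupling = bulk_coupling,
    seed = as.integer(seed)
  )
  if (cfg$n_taxa < 10) abort("n_taxa must be at least 10")
  if (cfg$n_samples_per_group < 2) abort("need at least 2 replicates per group")
  if (cfg$bulk_depth < 100 || cfg$culturome_depth < 100) {
    abort("sequencing depths must be at least 100")
  }
  fracs <- c(
    cfg$soil_effect_depth, cfg$culturability_depth,
    cfg$culturable_clade_fraction, cfg$clade_knockout_prob,
    cfg$establishment_failure, cfg$bulk_coupling
  )
  if (any(fracs < 0 | fracs > 1)) abort("fractions and depths must lie in [0, 1]")
  if (cfg$lognormal_sigma < 0 || cfg$amplification_sigma < 0 ||
    cfg$soil_effect_sigma < 0) {
    abort("sigmas must be non-negative")
  }
  structure(cfg, class = "cdiv_sim_config")
}

#' Simulate a phylogeny
#'
#' Pure-birth (Yule) tree via [ape::rphylo()], rescaled to unit height.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A rooted, ultrametric `phylo` tree of height 1 with tips
#'   `t0001, t0002, ...`.
#' @export
simulate_tree <- function(n_taxa, seed = NULL) {
  if (n_taxa < 2) abort("n_taxa must be at least 2")
  with_seed_maybe(seed, {
    tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
    tree$tip.label <- sprintf("t%04d", seq_len(n_taxa))
    tree
  })
}

# clade memberships cut at `depth` (fraction of unit tree height):
# tips with MRCA within `depth` of the tips, i.e. cophenetic <= 2 * depth
clades_at_depth <- function(hc, depth) {
  n <- length(hc$labels)
  if (depth <= 0) {
    return(setNames(seq_len(n), hc$labels))
  }
  cutree(hc, h = 2 * depth)
}

# per-soil clade-level differentiation at nested scales spanning (0, depth]:
# each clade at each scale is knocked out of one soil (probability halving
# with each coarser scale, `p_knock` at the finest) and carries an
# opposite-signed log-normal abundance shift. The process depends only on
# `depth`, so two fractions run at the same depth are exchangeable.
soil_differentiation <- function(hc, depth, n_scales, p_knock, sigma_total) {
  n <- length(hc$labels)
  kept <- matrix(TRUE, n, 2, dimnames = list(hc$labels, c("SP", "CZ")))
  shift <- matrix(0, n, 2, dimnames = dimnames(kept))
  if (depth <= 0) {
    return(list(kept = kept, shift = shift))
  }
  # fine scales carry most of the differentiation (soil endemism is a
  # close-relative phenomenon); weights halve with each coarser scale
  w <- 2^(seq_len(n_scales) - n_scales)
  sigma_scales <- sigma_total * sqrt(w / sum(w))
  for (s in seq_len(n_scales)) {
    # s = 1 is the coarsest scale (full `depth`), s = n_scales the finest
    cl <- clades_at_depth(hc, depth / 2^(s - 1))
    k <- max(cl)
    p_scale <- p_knock * w[s]
    sigma_scale <- sigma_scales[s]
    for (soil in 1:2) {
      knocked <- runif(k) < p_scale
      kept[, soil] <- kept[, soil] & !knocked[cl]
    }
    delta <- rnorm(k, 0, sigma_scale)
    shift[, 1] <- shift[, 1] + delta[cl]
    shift[, 2] <- shift[, 2] - delta[cl]
  }
  list(kept = kept, shift = shift)
}

# random whole-clade selection targeting `fraction` of the taxa
select_culturable <- function(cl, fraction) {
  n <- length(cl)
  target <- fraction * n
  sizes <- table(cl)
  ids <- sample(names(sizes)) # random clade order
  total <- 0
  chosen <- character(0)
  for (id in ids) {
    sz <- sizes[[id]]
    if (abs(total + sz - target) < abs(total - target)) {
      chosen <- c(chosen, id)
      total <- total + sz
    }
  }
  if (!length(chosen)) chosen <- sample(names(sizes), 1)
  as.character(cl) %in% chosen
}

#' Simulate a paired bulk/culturome dataset
#'
#' Generates a tree, a count table over all four (soil, fraction) groups, a
#' metadata table and a per-taxon truth table. Bulk abundances are
#' log-normal with clade-level soil differentiation at
#' `soil_effect_depth`; the culturome holds whole clades (cut at
#' `culturability_depth`) totalling `culturable_clade_fraction` of taxa,
#' with its own soil differentiation at `culturability_depth`, fresh
#' log-normal growth potentials (no bulk-abundance relationship unless
#' `bulk_coupling > 0`), and per-replicate log-normal amplification noise.
#' Counts are multinomial draws at the configured depths, so every sample
#' sums exactly to its depth.
#'
#' @param config A `cdiv_sim_config` from [simulation_config()].
#' @return A `cdiv_simulation` list: `table`, `tree`, `metadata`, `truth`,
#'   `config`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  if (!inherits(config, "cdiv_sim_config")) {
    abort("`config` must come from simulation_config()")
  }
  if (config$culturable_clade_fraction == 0) {
    abort("culturable_clade_fraction = 0 would give an empty culturome")
  }
  cfg <- config
  withr::with_seed(cfg$seed, {
    tree <- simulate_tree(cfg$n_taxa)
    taxa <- tree$tip.label
    coph <- stats::cophenetic(tree)[taxa, taxa]
    hc <- hclust(as.dist(coph), method = "single")
    hc$labels <- taxa

    base_log <- rnorm(cfg$n_taxa, 0, cfg$lognormal_sigma)
    growth_log <- rnorm(cfg$n_taxa, 0, cfg$lognormal_sigma)

    bulk_eff <- soil_differentiation(
      hc, cfg$soil_effect_depth, cfg$n_scales,
      cfg$clade_knockout_prob, cfg$soil_effect_sigma
    )
    cult_eff <- soil_differentiation(
      hc, cfg$culturability_depth, cfg$n_scales,
      cfg$clade_knockout_prob, cfg$soil_effect_sigma
    )
    # culturability is a clade-level trait shared by both soils; which
    # members of a broad culturable clade establish on the plates is
    # idiosyncratic per soil (within-clade competition from a composite
    # inoculum), so establishment failure scales with clade breadth
    cult_clades <- clades_at_depth(hc, cfg$culturability_depth)
    culturable <- select_culturable(cult_clades, cfg$culturable_clade_fraction)
    clade_size <- as.vector(table(cult_clades)[as.character(cult_clades)])
    p_est <- cfg$establishment_failure * pmax(0, 1 - 3 / clade_size)
    establish <- vapply(1:2, function(s) runif(cfg$n_taxa) >= p_est, logical(cfg$n_taxa))
    # competition produces winners, not extinctions: every culturable clade
    # keeps at least its fastest-growing member on each soil's plates
    for (s in 1:2) {
      for (id in unique(cult_clades[culturable])) {
        members <- which(cult_clades == id & culturable)
        if (!any(establish[members, s])) {
          establish[members[which.max(growth_log[members])], s] <- TRUE
        }
      }
    }
    # nor can cultivation recover nothing at all: if the differentiation
    # knockouts removed every culturable clade from one soil, the largest
    # such clade is restored there
    for (s in 1:2) {
      sel <- which(culturable)
      if (length(sel) && !any(cult_eff$kept[sel, s])) {
        biggest <- names(which.max(table(cult_clades[sel])))
        cult_eff$kept[sel[cult_clades[sel] == biggest], s] <- TRUE
      }
    }

    soils <- c("SP", "CZ")
    nrep <- cfg$n_samples_per_group

    # expected bulk relative abundances per soil
    w_bulk <- vapply(1:2, function(s) {
      exp(base_log + bulk_eff$shift[, s]) * bulk_eff$kept[, s]
    }, double(cfg$n_taxa))
    # expected culturome abundances before replicate noise
    cc <- cfg$bulk_coupling
    u_cult <- vapply(1:2, function(s) {
      fresh <- exp(growth_log + cult_eff$shift[, s]) * cult_eff$kept[, s] * establish[, s]
      (w_bulk[, s]^cc) * (fresh^(1 - cc)) * culturable
    }, double(cfg$n_taxa))
    if (any(colSums(w_bulk) == 0)) abort("a bulk community is empty; lower knockout settings")
    if (any(colSums(u_cult) == 0)) abort("a culturome community is empty; raise culturable_clade_fraction")

    draw <- function(weights, depth) drop(rmultinom(1, depth, weights))
    cols <- list()
    meta <- list()
    for (s in 1:2) {
      for (r in seq_len(nrep)) {
        id <- sprintf("bs%s_%d", soils[s], r)
        cols[[id]] <- draw(w_bulk[, s], cfg$bulk_depth)
        meta[[id]] <- tibble::tibble(
          sample_id = id, soil_type = soils[s], fraction = "bulk", replicate = r
        )
      }
    }
    for (s in 1:2) {
      for (r in seq_len(nrep)) {
        id <- sprintf("g%s_%d", soils[s], r)
        amp <- exp(rnorm(cfg$n_taxa, 0, cfg$amplification_sigma))
        cols[[id]] <- draw(u_cult[, s] * amp, cfg$culturome_depth)
        meta[[id]] <- tibble::tibble(
          sample_id = id, soil_type = soils[s], fraction = "culturome", replicate = r
        )
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- taxa

    truth <- tibble::tibble(
      taxon_id = taxa,
      base_log_abundance = base_log,
      growth_log_potential = growth_log,
      culturable = culturable,
      established_SP = establish[, 1],
      established_CZ = establish[, 2],
      bulk_kept_SP = bulk_eff$kept[, 1],
      bulk_kept_CZ = bulk_eff$kept[, 2],
      bulk_soil_effect = bulk_eff$shift[, 1] - bulk_eff$shift[, 2],
      cult_kept_SP = cult_eff$kept[, 1],
      cult_kept_CZ = cult_eff$kept[, 2],
      cult_soil_effect = cult_eff$shift[, 1] - cult_eff$shift[, 2]
    )

    structure(
      list(
        table = counts_to_table(counts),
        tree = tree,
        metadata = dplyr::bind_rows(meta),
        truth = truth,
        config = cfg
      ),
      class = "cdiv_simulation"
    )
  })
}

#' @export
print.cdiv_simulation <- function(x, ...) {
  cat(
    "simulated dataset:", nrow(x$table), "taxa,",
    nrow(x$metadata), "samples (seed", x$config$seed, ")\n"
  )
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the count table, newick tree, metadata and truth tables into a
#' directory using the package's on-disk formats.
#'
#' @param sim A `cdiv_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_phylotype_table(sim$table, file.path(dir, "table.tsv"))
  write_phylogeny(sim$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
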