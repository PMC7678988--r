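#' Read a phylotype count table
#'
#' Expects the common amplicon-table dialect: TSV with taxa as rows, a first
#' column named `taxon_id`, and one integer column per sample.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `taxon_id` and one numeric column per sample.
#' @export
read_phylotype_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  # readr warnings on malformed input are redundant with the validation
  # errors below
  tab <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    taxon_id = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE))
  if (!"taxon_id" %in% names(tab)) {
    abort(paste0("malformed count table (no `taxon_id` column): ", path))
  }
  as_count_matrix(tab) # validation only
  tab
}

#' Write a phylotype count table
#'
#' @param table Phylotype table (see [read_phylotype_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phylotype_table <- function(table, path) {
  as_count_matrix(table)
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `soil_type` (SP/CZ), `fraction`
#' (bulk/culturome) and `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    soil_type = readr::col_character(),
    fraction = readr::col_character(),
    replicate = readr::col_integer()
  ), progress = FALSE)
  check_metadata(meta)
  meta
}

#' Read a ranked taxonomy table
#'
#' TSV with a `taxon_id` column and one column per rank
#' (domain..species); empty strings mark unassigned ranks.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `taxon_id` plus rank columns.
#' @export
read_taxonomy_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tax <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  if (!"taxon_id" %in% names(tax)) {
    abort(paste0("malformed taxonomy table (no `taxon_id` column): ", path))
  }
  tax
}

#' Read a rooted phylogeny with branch lengths
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_phylogeny <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tree <- tryCatch(ape::read.tree(path),
    error = function(e) abort(paste0("malformed newick in ", path, ": ", conditionMessage(e)))
  )
  if (is.null(tree)) abort(paste0("malformed newick in ", path))
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to newick
#'
#' Branch lengths are written with 15 significant digits so trees survive a
#' round trip to within 1e-12 relative error.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output newick path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, path, digits = 15)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("tree must be an ape `phylo` object")
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("tree has negative branch lengths")
  invisible(tree)
}

#' Load and cross-validate a dataset
#'
#' Reads the count table, tree and metadata (plus an optional taxonomy table)
#' and enforces mutual consistency: samples missing from the metadata are an
#' error, while table taxa absent from the tree are dropped with a warning
#' and returned in `rejected` (cophenetic analyses require tree membership;
#' grafting would invent branch lengths).
#'
#' @param table_path,tree_path,metadata_path,taxonomy_path File paths;
#'   `taxonomy_path` may be `NULL`.
#' @return A list with elements `table`, `tree`, `metadata`, `taxonomy`
#'   (or `NULL`) and `rejected` (character vector of dropped taxon ids).
#' @export
load_dataset <- function(table_path, tree_path, metadata_path,
                         taxonomy_path = NULL) {
  table <- read_phylotype_table(table_path)
  tree <- read_phylogeny(tree_path)
  metadata <- read_sample_metadata(metadata_path)
  taxonomy <- if (!is.null(taxonomy_path)) read_taxonomy_table(taxonomy_path)

  sample_ids <- setdiff(names(table), "taxon_id")
  check_metadata(metadata, sample_ids)

  rejected <- setdiff(table$taxon_id, tree$tip.label)
  if (length(rejected)) {
    warn(paste0(
      length(rejected), " taxa absent from the tree were dropped: ",
      paste(head(rejected, 5), collapse = ", "),
      if (length(rejected) > 5) ", ..."
    ))
    table <- table[!table$taxon_id %in% rejected, , drop = FALSE]
  }
  if (nrow(table) < 1) abort("no table taxa found in the tree")

  extra_tips <- setdiff(tree$tip.label, table$taxon_id)
  if (length(extra_tips)) {
    tree <- ape::drop.tip(tree, extra_tips)
  }
  if (!is.null(taxonomy)) {
    taxonomy <- taxonomy[taxonomy$taxon_id %in% table$taxon_id, , drop = FALSE]
  }

  list(
    table = table, tree = tree, metadata = metadata,
    taxonomy = taxonomy, rejected = rejected
  )
}

#' Write an analysis report
#'
#' Serialises a named list of results (statistics, parameters, seeds) to a
#' single machine-readable JSON file. Values survive a round trip at full
#' double precision; `NaN`/`NA` statistics are kept as explicit nulls with a
#' flag rather than dropped.
#'
#' @param results Named list of results. May be empty.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (length(results) && is.null(names(results))) {
    abort("`results` must be a named list")
  }
  payload <- list(
    generator = "cdiv",
    version = as.character(utils::packageVersion("cdiv")),
    results = flag_missing(results)
  )
  ok <- tryCatch(
    {
      jsonlite::write_json(payload, path,
        auto_unbox = TRUE, digits = NA, null = "null", na = "null"
      )
      TRUE
    },
    error = function(e) abort(paste0("cannot write report to ", path, ": ", conditionMessage(e)))
  )
  invisible(path)
}

# recursively replace non-finite scalars with null + flag marker
flag_missing <- function(x) {
  if (is.list(x)) {
    lapply(x, flag_missing)
  } else if (is.numeric(x) && length(x) == 1 && !is.finite(x)) {
    list(value = NULL, flag = "undefined")
  } else {
    x
  }
}

#' Read back an analysis report
#'
#' @param path Path written by [write_report()].
#' @return The deserialised report list.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
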