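# internal helpers shared across modules

#' Convert a phylotype table to a counts matrix
#'
#' Phylotype tables travel through the package as wide tibbles: a `taxon_id`
#' column followed by one numeric column per sample. This converts to the
#' taxa-by-samples integer matrix used internally, validating on the way.
#'
#' @param table A phylotype table (data frame, `taxon_id` + sample columns).
#' @param check Validate counts (non-negative, integral, unique ids).
#' @return Numeric matrix, taxa in rows (named), samples in columns (named).
#' @keywords internal
#' @noRd
as_count_matrix <- function(table, check = TRUE) {
  if (!is.data.frame(table) || !"taxon_id" %in% names(table)) {
    abort("`table` must be a data frame with a `taxon_id` column.")
  }
  ids <- as.character(table[["taxon_id"]])
  m <- as.matrix(table[setdiff(names(table), "taxon_id")])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (check) {
    if (anyDuplicated(ids)) abort("duplicate taxon_id values in table")
    if (anyDuplicated(colnames(m))) abort("duplicate sample ids in table")
    if (ncol(m) < 1) abort("table has no sample columns")
    if (anyNA(m)) abort("counts contain missing values")
    if (any(m < 0)) abort("counts must be non-negative")
    if (any(abs(m - round(m)) > 1e-8)) abort("counts must be integers")
  }
  m
}

# matrix (taxa x samples) -> wide tibble with taxon_id first
counts_to_table <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(taxon_id = rownames(m)),
    tibble::as_tibble(m)
  )
}

# run `expr` under a fixed RNG state when `seed` is given, untouched otherwise
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

check_metadata <- function(metadata, sample_ids = NULL) {
  req <- c("sample_id", "soil_type", "fraction")
  missing_cols <- setdiff(req, names(metadata))
  if (length(missing_cols)) {
    abort(paste0("metadata lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(metadata$soil_type %in% c("SP", "CZ"))) {
    abort("soil_type must be 'SP' or 'CZ'")
  }
  if (!all(metadata$fraction %in% c("bulk", "culturome"))) {
    abort("fraction must be 'bulk' or 'culturome'")
  }
  if (anyDuplicated(metadata$sample_id)) abort("duplicate sample_id in metadata")
  if (!is.null(sample_ids)) {
    absent <- setdiff(sample_ids, metadata$sample_id)
    if (length(absent)) {
      abort(paste0(
        "samples missing from metadata: ", paste(absent, collapse = ", ")
      ))
    }
  }
  invisible(metadata)
}

# ids of samples in one (soil_type, fraction) group
group_samples <- function(metadata, soil_type = NULL, fraction = NULL) {
  keep <- rep(TRUE, nrow(metadata))
  if (!is.null(soil_type)) keep <- keep & metadata$soil_type == soil_type
  if (!is.null(fraction)) keep <- keep & metadata$fraction == fraction
  metadata$sample_id[keep]
}

# square labelled matrix from a dist, or pass a matrix through
dist_to_matrix <- function(d) {
  if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
}

check_distance_matrix <- function(d, arg = "D") {
  m <- dist_to_matrix(d)
  if (nrow(m) != ncol(m)) abort(paste0("`", arg, "` must be square"))
  if (is.null(rownames(m))) abort(paste0("`", arg, "` must have ids as dimnames"))
  if (max(abs(m - t(m))) > 1e-8) abort(paste0("`", arg, "` must be symmetric"))
  if (any(diag(m) != 0)) abort(paste0("`", arg, "` must have a zero diagonal"))
  if (any(m < -1e-12)) abort(paste0("`", arg, "` must be non-negative"))
  m
}
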