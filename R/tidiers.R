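#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PERMANOVA result
#'
#' @param x A `cdiv_permanova`.
#' @param ... Unused.
#' @return One-row tibble with `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`, `df_between`, `df_within`.
#' @export
tidy.cdiv_permanova <- function(x, ...) {
  tibble::tibble(
    pseudo_F = x$pseudo_F,
    R2 = x$R2,
    p_value = x$p_value,
    n_permutations = x$n_permutations,
    df_between = x$df[1],
    df_within = x$df[2]
  )
}

#' @rdname tidy.cdiv_permanova
#' @export
glance.cdiv_permanova <- function(x, ...) tidy(x, ...)

#' Tidy a PCoA ordination
#'
#' @param x A `cdiv_pcoa`.
#' @param ... Unused.
#' @return The coordinates tibble (`sample_id` + `Axis.k` columns).
#' @export
tidy.cdiv_pcoa <- function(x, ...) x$coordinates

#' @rdname tidy.cdiv_pcoa
#' @export
glance.cdiv_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_axes = sum(x$eigenvalues > 0),
    proportion_axis1 = x$proportion_explained[1],
    proportion_axis2 = x$proportion_explained[2]
  )
}
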