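#' Plot rarefaction curves
#'
#' @param curve Tibble from [rarefaction_curve()].
#' @param metadata Optional sample metadata; when given, curves are
#'   coloured by (soil type, fraction) group.
#' @return A ggplot.
#' @export
plot_rarefaction <- function(curve, metadata = NULL) {
  dat <- curve
  if (!is.null(metadata)) {
    dat <- dplyr::left_join(dat, metadata, by = "sample_id")
    dat$group <- paste(dat$soil_type, dat$fraction)
  } else {
    dat$group <- dat$sample_id
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$depth, y = .data$mean_richness,
    group = .data$sample_id, colour = .data$group
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "reads subsampled", y = "mean observed phylotypes", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Ordination plot for a PCoA result
#'
#' @param object A `cdiv_pcoa`.
#' @param metadata Optional sample metadata for colouring/shaping points.
#' @param ... Unused.
#' @return A ggplot of the first two axes.
#' @export
autoplot.cdiv_pcoa <- function(object, metadata = NULL, ...) {
  dat <- object$coordinates
  lab <- function(i) {
    sprintf("Axis %d (%.1f%%)", i, 100 * object$proportion_explained[i])
  }
  p <- if (!is.null(metadata)) {
    dat <- dplyr::left_join(dat, metadata, by = "sample_id")
    ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$Axis.1, y = .data$Axis.2,
      colour = .data$soil_type, shape = .data$fraction
    ))
  } else {
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2))
  }
  p + ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot divergence curves with their linear fits
#'
#' @param ... Tibbles from [divergence_curve()] (typically one per
#'   fraction).
#' @param min_taxa Fit-eligibility cutoff shown as the fitted-line extent.
#' @return A ggplot of shared percentage against merged-taxon fraction.
#' @export
plot_divergence_curves <- function(..., min_taxa = 50) {
  curves <- dplyr::bind_rows(...)
  dat <- curves |>
    dplyr::group_by(.data$fraction) |>
    dplyr::mutate(x = 1 - .data$n_taxa / .data$n_taxa[1]) |>
    dplyr::ungroup()
  eligible <- dplyr::filter(dat, .data$n_taxa >= min_taxa)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$x, y = .data$shared_pct, colour = .data$fraction
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(
      data = eligible, method = "lm", formula = y ~ x, se = FALSE
    ) +
    ggplot2::labs(
      x = "fraction of taxa merged", y = "% clusters shared between soils",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
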