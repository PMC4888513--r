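# ggplot2 figures for the main result types.

#' Plot an expression saturation curve
#'
#' Median cumulative count of threshold-passing genes against the number
#' of samples (or DE sets), with the permutation min-max band.
#'
#' @param curve A `saturation_curve` tibble.
#' @return A ggplot object.
#' @export
plot_saturation <- function(curve) {
  has_thr <- "threshold" %in% names(curve)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$median,
                                           colour = .data$label,
                                           fill = .data$label)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "samples included", y = "genes with evidence",
                  colour = "class", fill = "class") +
    ggplot2::theme_minimal()
  if (has_thr) {
    p <- p + ggplot2::facet_wrap(~threshold,
                                 labeller = ggplot2::label_both)
  }
  p
}

#' @export
autoplot.saturation_curve <- function(object, ...) plot_saturation(object)

#' Plot cumulative proportion of clusters under omega thresholds
#'
#' @param curves Output of [omega_cumulative()].
#' @return A ggplot object.
#' @export
plot_omega_cumulative <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$threshold,
                                       y = .data$proportion,
                                       colour = .data$category)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::labs(x = expression(omega ~ "threshold"),
                  y = "cumulative proportion of clusters",
                  colour = "cluster category") +
    ggplot2::theme_minimal()
}

#' Plot per-class distributions of gene features
#'
#' @param evidence Classified evidence tibble.
#' @param features Feature columns to show.
#' @return A ggplot object (boxplots, one facet per feature, free y).
#' @export
plot_class_features <- function(evidence,
                                features = c("transcript_length", "n_exons",
                                             "gc", "contig_percentile")) {
  long <- evidence |>
    dplyr::select(dplyr::all_of(c("class", features))) |>
    tidyr::pivot_longer(dplyr::all_of(features), names_to = "feature")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$class)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot selection results as a dN/dS distribution per dataset
#'
#' @param object A `selection_results` tibble (stacked datasets, with or
#'   without a `category` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.selection_results <- function(object, ...) {
  dat <- dplyr::filter(object, !is.na(.data$omega))
  aes <- if ("category" %in% names(dat)) {
    ggplot2::aes(x = .data$omega, colour = .data$category)
  } else {
    ggplot2::aes(x = .data$omega)
  }
  ggplot2::ggplot(dat, aes) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~dataset) +
    ggplot2::coord_cartesian(xlim = c(0, 2)) +
    ggplot2::labs(x = expression(hat(omega)), y = "cumulative proportion") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
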