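#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metagene profile
#'
#' Line plot of average density against distance from the anchor, with
#' optional wave-front markers drawn the way elongation-rate figures mark
#' the background crossing.
#'
#' @param object A `metagene_profile`.
#' @param wavefront Optional `wavefront` (or list of them) to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metagene_profile <- function(object, wavefront = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position / 1000,
                                        y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = sprintf("distance from %s (kb)", toupper(object$anchor)),
      y = "normalized reads (RPM/bin)",
      subtitle = sprintf("%d genes, %d bp bins", object$n_genes,
                         object$bin_size)) +
    ggplot2::theme_classic()
  if (!is.null(wavefront)) {
    wfs <- if (inherits(wavefront, "wavefront")) list(wavefront) else wavefront
    for (wf in wfs) {
      p <- p +
        ggplot2::geom_vline(xintercept = wf$position / 1000,
                            linetype = "dotted") +
        ggplot2::geom_hline(yintercept = wf$background,
                            linetype = "dashed", colour = "grey50")
    }
  }
  p
}

#' Plot a peak feature distribution
#'
#' Side-by-side bars of the observed per-category peak fractions and the
#' genome-wide bp fractions (the uniform-placement expectation).
#'
#' @param dist Output of [feature_distribution()].
#' @return A ggplot object.
#' @export
plot_feature_distribution <- function(dist) {
  long <- tidyr::pivot_longer(
    dist, c("peak_fraction", "genome_fraction"),
    names_to = "set", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$fraction,
                                     fill = .data$set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7,
                             labels = c(genome_fraction = "genome bp",
                                        peak_fraction = "peaks")) +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_classic()
}

#' Plot fold-change classes of quantified windows
#'
#' MA-style scatter: mean normalised count against fold change, coloured
#' by class, with the classifier cutoffs drawn.
#'
#' @param diff Output of [fold_change()].
#' @param fc_cut The cutoff used (for the guide lines; default 1.5).
#' @return A ggplot object.
#' @export
plot_fold_change <- function(diff, fc_cut = 1.5) {
  df <- dplyr::mutate(diff,
                      mean_count = (.data$count_wt + .data$count_null) / 2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_count, y = .data$fc,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = c(fc_cut, 1 / fc_cut),
                        linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b",
                                            down = "#2980b9",
                                            unchanged = "grey60")) +
    ggplot2::labs(x = "mean normalized count", y = "fold change (null/wt)",
                  colour = NULL) +
    ggplot2::theme_classic()
}
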