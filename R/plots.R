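#' Ovary-testis piRNA expression scatterplot
#'
#' Per-family normalized piRNA levels in ovary (y) versus testis (x) on
#' log10 axes, with sex-biased families (fold change beyond the threshold)
#' highlighted and the x = y diagonal drawn.
#'
#' @param levels Output of [normalize_and_classify()].
#' @return A ggplot object.
#' @export
plot_pirna_scatter <- function(levels) {
  ggplot2::ggplot(levels, ggplot2::aes(
    x = .data$testis_norm + 1, y = .data$ovary_norm + 1,
    colour = .data$sex_bias_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(
      ovary_biased = "firebrick", testis_biased = "orange",
      unbiased = "grey40")) +
    ggplot2::labs(
      x = "testis piRNAs per million miRNAs (+1)",
      y = "ovary piRNAs per million miRNAs (+1)",
      colour = "sex bias") +
    ggplot2::theme_minimal()
}

#' Size distribution of annotated TE insertions
#'
#' Histogram of insertion completeness (genomic span over consensus length)
#' per TE class, with the full-length boundary marked.
#'
#' @param insertions Insertion tibble from [annotate_genome()].
#' @param consensus Consensus tibble carrying family ids (used only when a
#'   `te_class` column must be joined in); optional.
#' @param full_length_min Full-length boundary to draw (default 0.98).
#' @return A ggplot object.
#' @export
plot_te_landscape <- function(insertions, consensus = NULL,
                              full_length_min = 0.98) {
  ggplot2::ggplot(insertions, ggplot2::aes(x = .data$completeness)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = full_length_min, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "insertion length / consensus length",
                  y = "number of copies") +
    ggplot2::theme_minimal()
}
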