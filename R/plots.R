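# Quick-look plots for pipeline results.

#' Plot ROH segments along chromosomes
#'
#' One horizontal track per sample, segments drawn to genomic scale and
#' coloured by length class when present.
#'
#' @param segments Segment tibble from [call_roh()] or
#'   [call_roh_cohort()].
#' @return A ggplot object.
#' @export
plot_roh_segments <- function(segments) {
  p <- ggplot2::ggplot(segments,
                       ggplot2::aes(xmin = .data$start_bp / 1e6,
                                    xmax = .data$end_bp / 1e6,
                                    y = .data$sample_id))
  p <- if ("length_class" %in% names(segments)) {
    p + ggplot2::geom_linerange(
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
                   colour = .data$length_class), linewidth = 2)
  } else {
    p + ggplot2::geom_linerange(
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6),
      linewidth = 2)
  }
  p + ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "Position (Mb)", y = NULL, colour = "Length (kb)") +
    ggplot2::theme_minimal()
}

#' Plot per-species F_ROH distribution
#'
#' @param records Output of [f_roh()] with a `species` column.
#' @return A ggplot object.
#' @export
plot_froh <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$species, y = .data$f_roh)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = expression(F[ROH])) +
    ggplot2::theme_minimal()
}

#' Plot ROH islands along chromosomes
#'
#' @param islands Island tibble from [roh_islands()].
#' @return A ggplot object.
#' @export
plot_islands <- function(islands) {
  ggplot2::ggplot(islands,
                  ggplot2::aes(xmin = .data$start_bp / 1e6,
                               xmax = .data$end_bp / 1e6,
                               y = .data$species,
                               colour = .data$pct_population)) +
    ggplot2::geom_linerange(linewidth = 3) +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::labs(x = "Position (Mb)", y = NULL, colour = "% carriers") +
    ggplot2::theme_minimal()
}
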