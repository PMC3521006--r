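#' Plot a periodicity fit over the rebinned interphase series
#'
#' Bars show the rebinned series, the line the fitted sinusoid-plus-trend.
#'
#' @param object A `period_fit` from [fit_periodicity()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.period_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$value), fill = "steelblue",
                      width = diff(range(object$data$time_h)) /
                        max(nrow(object$data) - 1, 1) * 0.85) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red",
                       linewidth = 0.9) +
    ggplot2::labs(
      x = "time (h)", y = "interphase signal",
      title = if (object$identifiable) {
        sprintf("Estimated cell-cycle period: %.1f h", object$period)
      } else "No identifiable periodicity") +
    ggplot2::theme_minimal()
}

#' Plate heatmap of counts or B-scores at one timepoint
#'
#' @param counts Tidy count table (`array_id`, `row`, `col`, value column).
#' @param value Column to map to fill.
#' @param at_frame Frame index to show (default: the midpoint frame).
#' @return A ggplot, facetted by array.
#' @export
plot_plate <- function(counts, value = "interphase", at_frame = NULL) {
  if (is.null(at_frame)) {
    at_frame <- counts$frame[which.min(abs(counts$frame -
                                             stats::median(counts$frame)))]
  }
  dat <- dplyr::filter(counts, .data$frame == at_frame)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row,
                                    fill = .data[[value]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::facet_wrap(~array_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "column", y = "row", fill = value,
                  title = paste0(value, " at frame ", at_frame)) +
    ggplot2::theme_minimal()
}

#' Phenotype significance profile of selected genes
#'
#' Heatmap of -log10 p per time-frame and phenotype; the candidate rule
#' looks for mitosis significance at a frame with cell-death significance
#' at the same or the next frame.
#'
#' @param profiles Tibble from [phenotype_pvalues()].
#' @param genes Genes to show (default: first 6).
#' @param alpha Significance threshold drawn as a contour in the legend.
#' @return A ggplot.
#' @export
plot_phenotype_profile <- function(profiles, genes = NULL, alpha = 0.05) {
  if (is.null(genes)) genes <- utils::head(unique(profiles$gene), 6)
  dat <- dplyr::filter(profiles, .data$gene %in% genes)
  dat <- dplyr::mutate(dat, neglog_p = -log10(pmax(.data$p, 1e-16)),
                       significant = .data$p <= alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_frame,
                                    y = .data$phenotype,
                                    fill = .data$neglog_p)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(dat, .data$significant),
                        shape = 8, size = 1, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = expression(-log[10] ~ p)) +
    ggplot2::facet_grid(gene + sirna ~ .) +
    ggplot2::labs(x = "time-frame", y = NULL) +
    ggplot2::theme_minimal()
}
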