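#' Histogram of per-ASV heritability estimates
#'
#' Mirrors the usual presentation of microbiome-heritability scans: counts of
#' ASVs per heritability bin, faceted by broad- vs narrow-sense, with
#' reference lines at 0.1 and 0.2.
#'
#' @param object A `herit_scan` object.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.herit_scan <- function(object, bins = 40, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("asv_id", "H2", "h2")],
    cols = c("H2", "h2"), names_to = "measure", values_to = "estimate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(xintercept = 0.1, colour = "red",
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.2, colour = "blue",
                        linetype = "dashed") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "heritability estimate", y = "ASV count") +
    ggplot2::theme_minimal()
}

#' Bar chart of PERMANOVA components of variation
#'
#' @param object A `permanova_nested` object.
#' @param ... Unused.
#' @return A ggplot object showing the signed square-root component of
#'   variation per model term.
#' @export
autoplot.permanova_nested <- function(object, ...) {
  tab <- object$table
  tab <- tab[tab$term != "Total", ]
  tab$term <- factor(tab$term, levels = tab$term)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$term, y = .data$sqrt_cv)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = expression(sqrt(CV))) +
    ggplot2::theme_minimal()
}
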