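#' Plot the p-value density histogram of a scan
#'
#' The density histogram of `p_mls` over fit columns with a positive MLS
#' slope: a real scan with longevity-coupled columns piles mass near 0
#' while a trait-permuted control is flat.
#'
#' @param object A [run_scan()] result.
#' @param bins Number of bins over `[0, 1]`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot longscan_scan
#' @export
autoplot.longscan_scan <- function(object, bins = 20L, ...) {
  h <- pvalue_histogram(object, bins = bins)
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                                  y = .data$density)) +
    ggplot2::geom_col(width = 1 / bins, fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = expression(p[MLS]), y = "density",
                  title = "p-value density, fit columns with positive MLS slope") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare real and randomized-control p-value densities
#'
#' @param real,control [run_scan()] results from the same panel, the second
#'   scanned under [randomize_traits()].
#' @param bins Number of bins.
#' @return A ggplot object, faceted real vs control.
#' @export
plot_scan_comparison <- function(real, control, bins = 20L) {
  h <- bind_rows(
    mutate(pvalue_histogram(real, bins), set = "real"),
    mutate(pvalue_histogram(control, bins), set = "randomized control"))
  h$set <- factor(h$set, levels = c("real", "randomized control"))
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                                  y = .data$density)) +
    ggplot2::geom_col(width = 1 / bins, fill = "grey35") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~set) +
    ggplot2::labs(x = expression(p[MLS]), y = "density") +
    ggplot2::theme_minimal()
}

#' Plot domain aggregation of longevity-selected positions
#'
#' @param object A [domain_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of selected-position counts per domain.
#' @export
plot_domain_summary <- function(object, ...) {
  object$label <- paste(object$protein, object$name, sep = ": ")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$label, .data$n_selected),
                               y = .data$n_selected)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "longevity-selected positions") +
    ggplot2::theme_minimal()
}
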