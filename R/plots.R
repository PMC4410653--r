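# ggplot2 views of the two report types, plus broom-style generics.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot alignment accuracy by region category
#'
#' Bar chart of `fraction_correct` per category (ALL plus each region
#' label), annotated with the number of reads judged.
#'
#' @param object An `alignment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot alignment_report
#' @export
autoplot.alignment_report <- function(object, ...) {
  d <- object$summary
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$fraction_correct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("n=", .data$n)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = "region category", y = "fraction of correct alignments",
                  title = sprintf("Alignment accuracy (wiggle %d bp)", object$wiggle)) +
    ggplot2::theme_minimal()
}

#' Plot sensitivity/precision/F1 by type and size bin
#'
#' Heatmap of the chosen metric over the `(variant type, size bin)` grid,
#' marginals excluded.
#'
#' @param object A `variant_comparison`.
#' @param metric One of `"f1"`, `"tpr"`, `"ppv"`.
#' @param bins Size bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot variant_comparison
#' @export
autoplot.variant_comparison <- function(object, metric = c("f1", "tpr", "ppv"),
                                        bins = default_size_bins(), ...) {
  metric <- match.arg(metric)
  d <- stratify(object, bins)
  d <- d[d$type != "ALL" & d$bin != "ALL", , drop = FALSE]
  d$bin <- factor(d$bin, levels = bins$label[order(bins$lo)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$type,
                                  fill = .data[[metric]])) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[metric]])),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 1), na.value = "grey95") +
    ggplot2::labs(x = "variant size bin (bp)", y = "variant type",
                  fill = toupper(metric),
                  title = "Variant calling accuracy by type and size") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
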