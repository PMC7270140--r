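#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot between-location connectivity differences
#'
#' Diverging bar chart of per-cell convexity-minus-skull-base connectivity
#' (or centrality): positive bars mark cells more active in convexity
#' tumours, negative bars cells more active in skull base.
#'
#' @param fit An `immune_network_fit`.
#' @param metric `"connectivity"` or `"centrality"`.
#' @return A ggplot object.
#' @export
plot_location_differences <- function(fit, metric = c("connectivity",
                                                      "centrality")) {
  metric <- match.arg(metric)
  col <- paste0("delta_", metric)
  d <- fit$differences
  d <- d[order(d[[col]]), ]
  d$cell_type <- factor(d$cell_type, levels = d$cell_type)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[col]], y = .data$cell_type,
                                  fill = .data[[col]] > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(x = paste("Δ", metric, "(convexity − skull base)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_location_differences
#' @param object,... `autoplot` arguments (`object` is the fit).
#' @method autoplot immune_network_fit
#' @export
autoplot.immune_network_fit <- function(object, ...) {
  plot_location_differences(object, ...)
}

#' Plot estimated cell-fraction composition
#'
#' Stacked per-sample bars of the deconvolved immune fractions.
#'
#' @param object A `cell_fractions` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cell_fractions
#' @export
autoplot.cell_fractions <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                  fill = .data$cell_type)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "sample", y = "estimated fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot module eigengene scores by tumour location
#'
#' Boxplots of the meta-gene score per module, split by location -- the
#' visual behind the module-location association tests.
#'
#' @param object A `coexpress_fit`.
#' @param metadata Metadata tibble with `location`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coexpress_fit
#' @export
autoplot.coexpress_fit <- function(object, metadata, ...) {
  metadata <- validate_metadata(metadata)
  d <- tibble::as_tibble(object$metagenes, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "module",
                        values_to = "score") |>
    dplyr::left_join(metadata[, c("sample_id", "location")], by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$location, y = .data$score,
                                  fill = .data$location)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = NULL, y = "meta-gene score") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param roc Result of [location_classifier()] (or any list with
#'   `roc_points` and `auc`).
#' @return A ggplot object.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}
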