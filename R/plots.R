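#' Heatmap of posterior edge inclusion probabilities
#'
#' @param object A `network_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot network_fit
#' @export
autoplot.network_fit <- function(object, ...) {
  ed <- tidy(object)
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$target, y = .data$source,
                                   fill = .data$inclusion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred", limits = c(0, 1)) +
    ggplot2::labs(x = "target", y = "regulator",
                  fill = "P(edge)", title = "Posterior edge inclusion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' ROC and precision-recall curves
#'
#' @param object An `edge_curves` object (see [curves]).
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot edge_curves
#' @export
autoplot.edge_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                           colour = "grey60") +
      ggplot2::labs(x = "false positive rate", y = "true positive rate",
                    title = sprintf("ROC (AUROC = %.3f)", object$auroc)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall, y = .data$precision)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::labs(x = "recall", y = "precision",
                    title = sprintf("Precision-recall (AUPR = %.3f)", object$aupr)) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_minimal()
  }
}

#' Plot measured time series
#'
#' One panel per molecule, one line per (condition, replicate) series.
#'
#' @param dataset A [pert_dataset].
#' @param molecules Optional subset of molecules to show.
#' @return A ggplot object.
#' @export
plot_timeseries <- function(dataset, molecules = NULL) {
  df <- as_tibble(dataset)
  if (!is.null(molecules)) df <- df[df$molecule %in% molecules, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = factor(.data$condition),
                                   group = interaction(.data$condition,
                                                       .data$replicate))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~molecule, scales = "free_y") +
    ggplot2::labs(colour = "condition") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
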