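#' Plot a contact matrix
#'
#' Tile heat map of a (ground-truth or predicted) residue-residue contact
#' matrix in match-state coordinates: domain A positions on the vertical
#' axis, domain B on the horizontal.
#'
#' @param cm A [contact_matrix()].
#' @return A ggplot object.
#' @export
plot_contact_matrix <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  df <- tidyr::expand_grid(a = seq_len(nrow(cm$cells)),
                           b = seq_len(ncol(cm$cells))) |>
    mutate(value = as.vector(t(cm$cells)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                        fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "domain B match position", y = "domain A match position",
                  fill = if (cm$kind == "predicted_score") "score" else "contact",
                  title = sprintf("%s / %s (%s)", cm$family_id, cm$pair_id,
                                  cm$kind)) +
    ggplot2::theme_minimal()
  if (cm$kind == "predicted_score") {
    p + ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                      high = "firebrick", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_gradient(low = "white", high = "firebrick")
  }
}

#' Plot a metrics report
#'
#' Grouped bar chart of the overall per-method means of accuracy,
#' precision, recall, F1 and MCC.
#'
#' @param object A `metrics_report` (or `benchmark_result`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- object$overall |>
    tidyr::pivot_longer(all_of(c("accuracy", "precision", "recall",
                                 "f1", "mcc")),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric,
                           c("accuracy", "f1", "mcc", "precision", "recall")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = "mean over sequences", fill = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.metrics_report
#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  autoplot.metrics_report(object$report, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
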