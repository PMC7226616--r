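#' Plot per-metabolite detection rates
#'
#' Lollipop chart of detection rates, coloured by the sign of the mean
#' effect, with the selection threshold drawn as a dashed line.
#'
#' @param object A `stability_result`.
#' @param threshold Detection-rate threshold to draw (default 0.70).
#' @param top_n Show only the `top_n` highest-DR metabolites (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_result <- function(object, threshold = 0.70, top_n = 30,
                                      ...) {
  eff <- dplyr::slice_max(object$effects, .data$detection_rate, n = top_n,
                          with_ties = FALSE)
  eff$direction <- ifelse(eff$mean_effect >= 0, "positive", "negative")
  ggplot2::ggplot(eff, ggplot2::aes(
    x = stats::reorder(.data$metabolite, .data$detection_rate),
    y = .data$detection_rate, colour = .data$direction)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$metabolite, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Detection rate",
                  colour = "Mean effect") +
    ggplot2::theme_minimal()
}

#' Plot variance shares of a refit model
#'
#' @param object A `refit_model` with at least one feature.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.refit_model <- function(object, ...) {
  sh <- object$variance_shares
  if (nrow(sh) == 0) abort("The refit model has no features to plot.")
  ggplot2::ggplot(sh, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$share),
    y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Share of yield variance",
      subtitle = sprintf("subset %s, model R² = %.3f", object$subset,
                         object$r2)) +
    ggplot2::theme_minimal()
}
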