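#' Plot ion-score distributions
#'
#' Overlaid score histograms for two ion sets (typically IL-derived vs
#' general ions), mirroring the diagnostic used to check that a trained
#' scorer separates the classes.
#'
#' @param scores A data frame with columns `score` and `class` (a label per
#'   ion, e.g. `"il"` / `"general"`).
#' @param bins Histogram bins (default 30).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 30L) {
  stopifnot(all(c("score", "class") %in% names(scores)))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$score,
                                       fill = .data$class)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "ion score", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Parity plot for melting-point predictions
#'
#' @param predictions,truths Equal-length numeric vectors (kelvin).
#' @return A ggplot object with the identity line.
#' @export
plot_mpt_parity <- function(predictions, truths) {
  df <- tibble::tibble(pred = predictions, truth = truths)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "experimental melting point (K)",
                  y = "predicted melting point (K)") +
    ggplot2::theme_minimal()
}

#' Plot a 2-D chemical-space projection
#'
#' @param coords Tibble from [project_chemical_space()], optionally with an
#'   extra `class` column used for colour.
#' @return A ggplot object.
#' @export
plot_chemical_space <- function(coords) {
  stopifnot(all(c("x", "y") %in% names(coords)))
  p <- if ("class" %in% names(coords)) {
    ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$class))
  } else {
    ggplot2::ggplot(coords, ggplot2::aes(x = .data$x, y = .data$y))
  }
  p + ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pred_mpt_K)) +
    ggplot2::geom_histogram(bins = 40L, fill = "steelblue", alpha = 0.8) +
    ggplot2::labs(x = "predicted melting point (K)", y = "pairs") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
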