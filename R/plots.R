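#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a confusion matrix
#'
#' @param object A `pm_confusion`.
#' @param ... Unused.
#' @return A ggplot: decoded-vs-true incidence (%), rows ordered as in the
#'   matrix.
#' @exportS3Method ggplot2::autoplot
autoplot.pm_confusion <- function(object, ...) {
  df <- tidy.pm_confusion(object)
  df$true <- factor(df$true, levels = rev(rownames(object)))
  df$decoded <- factor(df$decoded, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$decoded, y = .data$true,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% of trials", limits = c(0, 100)) +
    ggplot2::labs(x = "decoded condition", y = "true condition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of a cross-temporal decoding map
#'
#' @param object A `pm_xtmap`.
#' @param ... Unused.
#' @return A ggplot: accuracy for each train/test window pair, with dashed
#'   lines at delay onset.
#' @exportS3Method ggplot2::autoplot
autoplot.pm_xtmap <- function(object, ...) {
  df <- tidy.pm_xtmap(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$test_start_ms,
                                   y = .data$train_start_ms,
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_hline(yintercept = 1000, linetype = "dashed", colour = "white") +
    ggplot2::geom_vline(xintercept = 1000, linetype = "dashed", colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "% correct") +
    ggplot2::labs(x = "testing window start (ms)",
                  y = "training window start (ms)",
                  title = paste(object$task, "task")) +
    ggplot2::theme_minimal()
}

#' Scatter of perceptual versus mnemonic discriminability
#'
#' One point per neuron, coloured by functional class, with the rectified
#' auROC floor at 0.5 on both axes.
#'
#' @param classifications Output of [classify_neurons()].
#' @return A ggplot.
#' @export
plot_discriminability <- function(classifications) {
  ggplot2::ggplot(classifications,
                  ggplot2::aes(x = .data$auroc_perceptual,
                               y = .data$auroc_mnemonic,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal(xlim = c(0.5, 1), ylim = c(0.5, 1)) +
    ggplot2::labs(x = "perceptual discriminability (auROC)",
                  y = "mnemonic discriminability (auROC)",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Error-incidence profile around the true direction
#'
#' @param profiles Tibble from [error_profile_repetitions()] (or a single
#'   [error_incidence_profile()] with a `rep` column added).
#' @return A ggplot of mean incidence at offsets 0, 90, -90, 180 with
#'   per-repetition points.
#' @export
plot_error_profile <- function(profiles) {
  profiles$offset_deg <- factor(profiles$offset_deg,
                                levels = c(-90, 0, 90, 180))
  mean_df <- profiles |>
    dplyr::group_by(.data$offset_deg) |>
    dplyr::summarise(incidence = mean(.data$incidence), .groups = "drop")
  ggplot2::ggplot(profiles, ggplot2::aes(x = .data$offset_deg,
                                         y = .data$incidence)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.3, colour = "grey50") +
    ggplot2::geom_col(data = mean_df, alpha = 0.4, fill = "steelblue") +
    ggplot2::labs(x = "decoded direction relative to true (deg)",
                  y = "incidence (%)") +
    ggplot2::theme_minimal()
}
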