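#' Plot cross-validated accuracies by modality
#'
#' Box plot of per-fold accuracies for every base modality and fusion
#' combination, with the chance level marked.
#'
#' @param object A `bci_cv_result`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.bci_cv_result <- function(object, ...) {
  df <- object$folds
  df$modality <- factor(df$modality,
                        levels = c("EEG", "HbR", "HbO", names(FUSION_SPECS)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modality, y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "accuracy (%)",
                  title = sprintf("%d x %d-fold cross-validation",
                                  object$repetitions, object$n_folds)) +
    ggplot2::theme_minimal()
}

#' Plot a channel-by-band discriminability map
#'
#' Tile map of signed r-squared values per channel and frequency band;
#' negative values (blue) mean lower band power during mental arithmetic.
#'
#' @param object A `bci_disc_map` from [sgn_r2_band_map()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.bci_disc_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$band, y = .data$channel,
                                       fill = .data$sgn_r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "sgn r²") +
    ggplot2::theme_minimal()
}

#' Plot the theoretical ITR curve with observed points
#'
#' Draws the two-class ITR as a function of accuracy for a given trial rate
#' and overlays observed accuracy/ITR pairs.
#'
#' @param accuracy Observed accuracies (percent), optionally named.
#' @param m Trials per minute.
#' @param n_classes Number of task types.
#'
#' @return A ggplot object.
#' @export
plot_itr_curve <- function(accuracy = numeric(0), m = 6, n_classes = 2) {
  grid <- tibble::tibble(p = seq(50.5, 100, by = 0.5))
  grid$itr <- compute_itr(grid$p, m = m, n_classes = n_classes)
  gg <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$p, y = .data$itr)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "accuracy (%)", y = "ITR (bits/min)") +
    ggplot2::theme_minimal()
  if (length(accuracy)) {
    pts <- tibble::tibble(p = as.numeric(accuracy),
                          itr = compute_itr(accuracy, m = m,
                                            n_classes = n_classes),
                          label = names(accuracy) %||%
                            as.character(seq_along(accuracy)))
    gg <- gg + ggplot2::geom_point(data = pts, color = "#b2182b")
  }
  gg
}
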