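stage_depth <- function(stages) {
  # conventional hypnogram layout: W on top, N3 at the bottom, REM
  # between W and N1
  depth <- c(W = 0, R = -1, N1 = -2, N2 = -3, N3 = -4)
  depth[as.character(stages)]
}

#' Plot a hypnogram
#'
#' Step plot of the stage sequence in the conventional clinical layout
#' (wake at the top, deep sleep at the bottom, REM just under wake).
#'
#' @param object A [hypnogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hypnogram
#' @export
autoplot.hypnogram <- function(object, ...) {
  df <- tibble::tibble(hours = object$epoch * attr(object, "epoch_seconds") / 3600,
                       depth = stage_depth(object$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$depth)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::scale_y_continuous(breaks = c(0, -1, -2, -3, -4),
                                labels = c("W", "R", "N1", "N2", "N3")) +
    ggplot2::labs(x = "Time (h)", y = "Stage",
                  title = paste("Hypnogram:", attr(object, "subject_id"))) +
    ggplot2::theme_minimal()
}

#' Expert vs predicted hypnogram panel
#'
#' @param true,pred [hypnogram()]s of equal length.
#' @return A ggplot object with the two hypnograms stacked.
#' @export
plot_hypnogram_pair <- function(true, pred) {
  stopifnot(nrow(true) == nrow(pred))
  df <- dplyr::bind_rows(
    tibble::tibble(hours = true$epoch * 30 / 3600,
                   depth = stage_depth(true$stage), which = "expert"),
    tibble::tibble(hours = pred$epoch * 30 / 3600,
                   depth = stage_depth(pred$stage), which = "predicted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hours, y = .data$depth,
                                   colour = .data$which)) +
    ggplot2::geom_step(linewidth = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~which, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(expert = "firebrick",
                                            predicted = "steelblue")) +
    ggplot2::scale_y_continuous(breaks = c(0, -1, -2, -3, -4),
                                labels = c("W", "R", "N1", "N2", "N3")) +
    ggplot2::labs(x = "Time (h)", y = "Stage") +
    ggplot2::theme_minimal()
}

#' Plot repeated-CV accuracies
#'
#' Boxplot of the held-out accuracy values (one per fold x repetition).
#'
#' @param object A [repeated_cv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$rep), y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = "Repetition", y = "Held-out accuracy",
                  title = sprintf("%s: %d x %d-fold CV", object$config$algorithm,
                                  object$config$reps, object$config$k)) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Tile heatmap of row-normalized confusion rates (true stage by row).
#'
#' @param object A [stage_metrics()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stage_metrics
#' @export
autoplot.stage_metrics <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion_rates))
  names(df) <- c("true", "predicted", "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(sleep_stages())) +
    ggplot2::labs(x = "Predicted stage", y = "Expert stage") +
    ggplot2::theme_minimal()
}
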