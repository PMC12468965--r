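#' Plot a metric report
#'
#' ggplot2 views of the evaluation machinery: ROC and precision-recall
#' curves, the calibration (reliability) diagram, the decision curve
#' against the treat-all/treat-none policies, and the confusion matrix as
#' a heatmap.
#'
#' @param object A [metric_report()].
#' @param which One of "roc", "pr", "calibration", "decision", "confusion".
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object,
                                   which = c("roc", "pr", "calibration",
                                             "decision", "confusion"),
                                   ...) {
  which <- match.arg(which)
  if (which != "confusion" && is.null(object$roc)) {
    stop_ctrender("This report was built without probabilities; only the confusion plot is available.")
  }
  switch(which,
    roc = ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr,
                                                   y = .data$tpr)) +
      ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
      ggplot2::geom_path(color = "#2C7FB8", linewidth = 0.8) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "False positive rate", y = "True positive rate",
                    title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
      ggplot2::theme_minimal(),
    pr = ggplot2::ggplot(object$pr, ggplot2::aes(x = .data$recall,
                                                 y = .data$precision)) +
      ggplot2::geom_path(color = "#D95F02", linewidth = 0.8) +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(x = "Recall", y = "Precision",
                    title = sprintf("Precision-recall (AP = %.3f)",
                                    object$average_precision)) +
      ggplot2::theme_minimal(),
    calibration = {
      cal <- object$calibration[!object$calibration$empty, ]
      ggplot2::ggplot(cal, ggplot2::aes(x = .data$mean_pred,
                                        y = .data$obs_freq)) +
        ggplot2::geom_abline(linetype = "dashed", color = "grey60") +
        ggplot2::geom_point(ggplot2::aes(size = .data$n), color = "#1B9E77") +
        ggplot2::geom_line(color = "#1B9E77") +
        ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
        ggplot2::labs(x = "Mean predicted probability",
                      y = "Observed frequency",
                      title = "Calibration (reliability) diagram") +
        ggplot2::theme_minimal()
    },
    decision = {
      dc <- tidyr::pivot_longer(object$decision, cols = c("net_benefit",
                                                          "treat_all",
                                                          "treat_none"),
                                names_to = "policy", values_to = "nb")
      ggplot2::ggplot(dc, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                       color = .data$policy)) +
        ggplot2::geom_line(linewidth = 0.8) +
        ggplot2::coord_cartesian(ylim = c(-0.1, NA)) +
        ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                      title = "Decision curve analysis", color = NULL) +
        ggplot2::theme_minimal()
    },
    confusion = {
      cm <- object$confusions[[1]]
      df <- tibble::tibble(
        truth = factor(c("positive", "positive", "negative", "negative"),
                       levels = c("positive", "negative")),
        pred = factor(c("positive", "negative", "positive", "negative"),
                      levels = c("positive", "negative")),
        n = c(cm$tp, cm$fn, cm$fp, cm$tn))
      ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                       fill = .data$n)) +
        ggplot2::geom_tile() +
        ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "white",
                           size = 5) +
        ggplot2::scale_fill_gradient(low = "#9ECAE1", high = "#08519C") +
        ggplot2::labs(x = "Predicted", y = "True",
                      title = sprintf("Confusion matrix (positive = %s)",
                                      cm$positive)) +
        ggplot2::theme_minimal() +
        ggplot2::theme(legend.position = "none")
    })
}

#' Display a cohort slice, its overlay, or a rendered candidate
#'
#' @param pixels A grayscale matrix (0-255 or -1..1) or an RGB array.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_slice <- function(pixels, title = NULL) {
  if (length(dim(pixels)) == 3) {
    H <- dim(pixels)[1]
    df <- expand.grid(row = seq_len(H), col = seq_len(dim(pixels)[2]))
    df$fill <- grDevices::rgb(pixels[, , 1], pixels[, , 2], pixels[, , 3],
                              maxColorValue = 255)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity()
  } else {
    if (min(pixels) < 0) pixels <- (pixels + 1) / 2 * 255
    H <- nrow(pixels)
    df <- expand.grid(row = seq_len(H), col = seq_len(ncol(pixels)))
    df$v <- as.numeric(pixels)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$v)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   limits = c(0, 255))
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_void() + ggplot2::theme(legend.position = "none")
}

#' Selection-mix bar chart
#'
#' Shows how often each renderer was selected per class, mirroring the
#' structure of the selection manifest.
#'
#' @param manifest A selection manifest tibble.
#' @return A ggplot object.
#' @export
plot_selection_mix <- function(manifest) {
  ggplot2::ggplot(manifest, ggplot2::aes(x = .data$selected_method,
                                         fill = .data$label)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "Selected renderer", y = "Samples", fill = NULL,
                  title = "Representative selection mix") +
    ggplot2::theme_minimal()
}
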