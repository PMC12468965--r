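#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metric report
#'
#' One row per class-metric pair (including the macro average), with
#' bootstrap confidence bounds where available.
#'
#' @param x A [metric_report()].
#' @param ... Unused.
#' @return A tibble: `class`, `metric`, `value`, `conf_low`, `conf_high`.
#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) {
  long <- tidyr::pivot_longer(x$metrics, cols = -"class",
                              names_to = "metric", values_to = "value")
  long$conf_low <- NA_real_
  long$conf_high <- NA_real_
  if (!is.null(x$ci)) {
    for (nm in names(x$ci)) {
      hit <- long$class == "macro" & long$metric == nm
      long$conf_low[hit] <- x$ci[[nm]]$lower
      long$conf_high[hit] <- x$ci[[nm]]$upper
    }
  }
  if (!is.null(x$auc)) {
    long <- dplyr::bind_rows(long, tibble::tibble(
      class = "macro", metric = "auc", value = x$auc,
      conf_low = if (!is.null(x$ci$auc)) x$ci$auc$lower else NA_real_,
      conf_high = if (!is.null(x$ci$auc)) x$ci$auc$upper else NA_real_))
  }
  long
}

#' Glance at a metric report
#'
#' @param x A [metric_report()].
#' @param ... Unused.
#' @return A one-row tibble of the macro metrics (plus AUC and n).
#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  mac <- x$metrics[x$metrics$class == "macro", ]
  tibble::tibble(n = x$n, acc = mac$acc, se = mac$se, sp = mac$sp,
                 pre = mac$pre, f_scr = mac$f_scr,
                 auc = x$auc %||% NA_real_)
}

#' Glance at a trained backbone
#'
#' @param x A `ctrender_backbone`.
#' @param ... Unused.
#' @return A one-row tibble: backbone name, epochs, learning rate, training
#'   accuracy.
#' @method glance ctrender_backbone
#' @export
glance.ctrender_backbone <- function(x, ...) {
  tibble::tibble(backbone = x$spec$name, epochs = x$spec$epochs,
                 learning_rate = x$spec$learning_rate,
                 classes = paste(x$classes, collapse = "/"),
                 train_accuracy = x$train_accuracy %||% NA_real_)
}

#' Tidy a pipeline run
#'
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @return A tibble with one row per evaluation scheme and metric.
#' @method tidy pipeline_run
#' @export
tidy.pipeline_run <- function(x, ...) {
  purrr::map_dfr(names(x$reports), function(nm) {
    out <- glance(x$reports[[nm]])
    dplyr::bind_cols(tibble::tibble(scheme = nm), out)
  })
}
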