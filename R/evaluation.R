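#' Confusion matrix counts
#'
#' Counts true/false positives/negatives of a binary view of the
#' predictions, with `positive` as the positive class and everything else
#' pooled as negative.
#'
#' @param y_true,y_pred Equal-length label vectors; predicted labels must
#'   come from the set of true labels.
#' @param positive The positive class label.
#' @return A `ct_confusion` object with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(y_true, y_pred, positive) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop_ctrender("`y_true` and `y_pred` must have equal length.")
  }
  known <- unique(y_true)
  if (!positive %in% known) {
    stop_ctrender(sprintf("Unknown positive label '%s'.", positive),
                  class = "ctrender_label_error")
  }
  if (!all(y_pred %in% known)) {
    stop_ctrender("`y_pred` contains labels absent from `y_true`.",
                  class = "ctrender_label_error")
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, positive = positive),
            class = "ct_confusion")
}

#' @export
print.ct_confusion <- function(x, ...) {
  cat(sprintf("<confusion vs '%s': tp=%d tn=%d fp=%d fn=%d>\n", x$positive,
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("Zero denominator for %s; reporting 0.", what))
    return(0)
  }
  num / den
}

metric_core <- function(cm) {
  tibble::tibble(
    se = safe_ratio(cm$tp, cm$fn + cm$tp, "sensitivity"),
    sp = safe_ratio(cm$tn, cm$fp + cm$tn, "specificity"),
    pre = safe_ratio(cm$tp, cm$fp + cm$tp, "precision"),
    f_scr = safe_ratio(2 * cm$tp, 2 * cm$tp + cm$fn + cm$fp, "f-score"),
    acc = safe_ratio(cm$tn + cm$tp, cm$tn + cm$tp + cm$fn + cm$fp, "accuracy"))
}

#' Macro-averaged classification metrics
#'
#' Sensitivity, specificity, precision, F-score and accuracy computed per
#' class (each class in turn as positive) and macro-averaged as the
#' unweighted mean across classes. Zero-denominator metrics contribute 0
#' with a warning rather than aborting a report.
#'
#' @param cms A list of [confusion()] objects, one per class.
#' @return A tibble with one row per class plus a `macro` row; columns
#'   `class`, `se`, `sp`, `pre`, `f_scr`, `acc`.
#' @export
macro_metrics <- function(cms) {
  if (length(cms) == 0) stop_ctrender("Need at least one confusion matrix.")
  per <- purrr::map_dfr(cms, function(cm) {
    dplyr::bind_cols(tibble::tibble(class = cm$positive), metric_core(cm))
  })
  macro <- dplyr::summarise(per, dplyr::across(c("se", "sp", "pre", "f_scr",
                                                 "acc"), mean))
  dplyr::bind_rows(per, dplyr::bind_cols(tibble::tibble(class = "macro"), macro))
}

per_class_confusions <- function(y_true, y_pred) {
  classes <- class_levels(y_true)
  lapply(classes, function(cl) confusion(y_true, y_pred, cl))
}

#' Patient-grouped data split
#'
#' Splits a cohort at the patient level so that all slices of one patient
#' stay on the same side of every split. Holdout stratifies the 70/30 (or
#' given ratio) split by patient label; k-fold builds label-stratified
#' patient folds that partition the cohort.
#'
#' @param images Cohort tibble with `image_id`, `patient_id`, `label`.
#' @param mode `"holdout"` or `"kfold"`.
#' @param ratio Training fraction for holdout.
#' @param k Number of folds for kfold.
#' @param seed Integer seed.
#' @return A `split_plan`: holdout has `train_ids`/`test_ids` (image ids);
#'   kfold has `folds`, a list of test-image-id vectors.
#' @export
grouped_split <- function(images, mode = c("holdout", "kfold"), ratio = 0.7,
                          k = 5, seed = 42) {
  mode <- match.arg(mode)
  stopifnot(all(c("image_id", "patient_id", "label") %in% names(images)))
  pat <- dplyr::distinct(images, .data$patient_id, .data$label)
  if (any(duplicated(pat$patient_id))) {
    stop_ctrender("A patient appears under two labels.",
                  class = "ctrender_label_error")
  }
  classes <- unique(pat$label)
  local_seed(seed, {
    if (mode == "holdout") {
      train_pat <- character(0)
      for (cl in classes) {
        ids <- sample(pat$patient_id[pat$label == cl])
        n_tr <- round(ratio * length(ids))
        train_pat <- c(train_pat, ids[seq_len(n_tr)])
      }
      structure(list(mode = "holdout", seed = seed, ratio = ratio,
                     train_ids = images$image_id[images$patient_id %in% train_pat],
                     test_ids = images$image_id[!images$patient_id %in% train_pat],
                     train_patients = train_pat,
                     test_patients = setdiff(pat$patient_id, train_pat)),
                class = "split_plan")
    } else {
      for (cl in classes) {
        if (sum(pat$label == cl) < k) {
          stop_ctrender(sprintf("Fewer than k=%d patients in class '%s'.", k, cl),
                        class = "ctrender_split_error")
        }
      }
      fold_of <- setNames(integer(nrow(pat)), pat$patient_id)
      for (cl in classes) {
        ids <- sample(pat$patient_id[pat$label == cl])
        fold_of[ids] <- rep_len(seq_len(k), length(ids))
      }
      folds <- lapply(seq_len(k), function(f) {
        images$image_id[fold_of[images$patient_id] == f]
      })
      structure(list(mode = "kfold", seed = seed, k = k, folds = folds,
                     fold_of_patient = fold_of),
                class = "split_plan")
    }
  })
}

#' ROC and precision-recall curves
#'
#' Threshold-sweep curves over the unique score values (ties cross a
#' threshold simultaneously), AUC by the trapezoid rule, and average
#' precision as the step-sum of precision over recall increments.
#'
#' @param y_true Binary labels.
#' @param scores Real-valued scores, larger meaning more positive.
#' @param positive Positive class label.
#' @return A list: `roc` tibble (`threshold`, `fpr`, `tpr`), `pr` tibble
#'   (`threshold`, `recall`, `precision`), `auc`, `average_precision`.
#' @export
roc_pr_curves <- function(y_true, scores, positive) {
  y_true <- as.character(y_true)
  if (length(unique(y_true)) < 2) {
    stop_ctrender("ROC needs both classes present in `y_true`.",
                  class = "ctrender_label_error")
  }
  stopifnot(length(y_true) == length(scores), all(is.finite(scores)))
  pos <- y_true == positive
  nP <- sum(pos)
  nN <- sum(!pos)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(pos & scores >= t) / nP, numeric(1))
  fpr <- vapply(th, function(t) sum(!pos & scores >= t) / nN, numeric(1))
  roc <- tibble::tibble(threshold = c(Inf, th), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  prec <- vapply(th, function(t) {
    npred <- sum(scores >= t)
    if (npred == 0) 1 else sum(pos & scores >= t) / npred
  }, numeric(1))
  pr <- tibble::tibble(threshold = th, recall = tpr, precision = prec)
  ap <- sum(diff(c(0, pr$recall)) * pr$precision)
  list(roc = roc, pr = pr, auc = auc, average_precision = ap)
}

#' Calibration (reliability) bins
#'
#' Equal-width probability bins with per-bin mean predicted probability,
#' observed positive frequency and count; empty bins are kept and flagged.
#'
#' @param y_true Labels.
#' @param probs Predicted probabilities of the positive class, in `[0, 1]`.
#' @param positive Positive class label.
#' @param n_bins Number of bins.
#' @return A tibble: `bin`, `lower`, `upper`, `n`, `mean_pred`, `obs_freq`,
#'   `empty`.
#' @export
calibration_bins <- function(y_true, probs, positive, n_bins = 10) {
  if (any(probs < 0 | probs > 1)) {
    stop_ctrender("`probs` must lie in [0, 1].", class = "ctrender_prob_error")
  }
  y <- as.character(y_true) == positive
  bin <- pmin(floor(probs * n_bins) + 1L, n_bins)
  purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- bin == b
    tibble::tibble(bin = b, lower = (b - 1) / n_bins, upper = b / n_bins,
                   n = sum(idx),
                   mean_pred = if (any(idx)) mean(probs[idx]) else NA_real_,
                   obs_freq = if (any(idx)) mean(y[idx]) else NA_real_,
                   empty = !any(idx))
  })
}

#' Decision-curve analysis
#'
#' Net benefit of thresholding the model's probabilities at each decision
#' threshold pt, compared with the treat-all and treat-none policies:
#' `NB(pt) = TP/N - (FP/N) * pt/(1-pt)`; treat-all substitutes the class
#' prevalence; treat-none is identically zero. Thresholds of exactly 0 or 1
#' are excluded (with a warning) since the weighting is undefined there.
#'
#' @param y_true Labels.
#' @param probs Positive-class probabilities.
#' @param positive Positive class label.
#' @param thresholds Decision thresholds in (0, 1).
#' @return A tibble: `threshold`, `net_benefit`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(y_true, probs, positive,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  drop <- thresholds <= 0 | thresholds >= 1
  if (any(drop)) {
    warn("Thresholds at 0 or 1 are excluded from the decision curve.")
    thresholds <- thresholds[!drop]
  }
  y <- as.character(y_true) == positive
  N <- length(y)
  prev <- mean(y)
  purrr::map_dfr(thresholds, function(pt) {
    pred <- probs >= pt
    w <- pt / (1 - pt)
    tibble::tibble(threshold = pt,
                   net_benefit = sum(y & pred) / N - sum(!y & pred) / N * w,
                   treat_all = prev - (1 - prev) * w,
                   treat_none = 0)
  })
}

#' Bootstrap percentile confidence interval for a metric
#'
#' Resamples evaluation cases with replacement, recomputes the metric, and
#' reports the percentile interval. Resamples on which the metric is
#' undefined (NA or error) are redrawn and counted.
#'
#' @param metric_fn Function `(y_true, y_out) -> scalar`.
#' @param y_true Labels.
#' @param y_out Predictions (vector) or probabilities aligned with `y_true`.
#' @param B Number of bootstrap resamples (>= 100).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A list: `estimate`, `lower`, `upper`, `level`, `B`, `redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, y_true, y_out, B = 1000, level = 0.95,
                         seed = 42) {
  stopifnot(B >= 100)
  n <- length(y_true)
  est <- metric_fn(y_true, y_out)
  redrawn <- 0L
  vals <- local_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        v <- tryCatch(metric_fn(y_true[idx],
                                if (is.matrix(y_out)) y_out[idx, , drop = FALSE]
                                else y_out[idx]),
                      error = function(e) NA_real_)
        if (!is.na(v)) return(v)
        redrawn <<- redrawn + 1L
        if (redrawn > 10L * B) {
          stop_ctrender("Metric undefined on almost every resample.")
        }
      }
    }, numeric(1))
  })
  if (redrawn > 0) inform(sprintf("%d bootstrap resamples redrawn.", redrawn))
  qs <- quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], level = level, B = B,
       redrawn = redrawn)
}

#' Assemble a full metric report
#'
#' Bundles everything the clinical-style evaluation emits for one set of
#' predictions: per-class and macro metrics, ROC/PR curves with AUC,
#' calibration bins, decision curve, and bootstrap confidence intervals for
#' accuracy, sensitivity, specificity, precision and AUC.
#'
#' @param y_true True labels.
#' @param y_pred Predicted labels.
#' @param probs Positive-class probabilities (optional; curves and CIs that
#'   need probabilities are skipped when absent).
#' @param positive Positive class label.
#' @param boot_B Bootstrap resamples (0 disables CIs).
#' @param seed Integer seed for the bootstrap.
#' @return A `metric_report` object.
#' @export
metric_report <- function(y_true, y_pred, probs = NULL,
                          positive = "mesothelioma", boot_B = 200, seed = 42) {
  cms <- per_class_confusions(y_true, y_pred)
  metrics <- macro_metrics(cms)
  rep <- list(confusions = cms, metrics = metrics, positive = positive,
              n = length(y_true))
  if (!is.null(probs)) {
    curves <- roc_pr_curves(y_true, probs, positive)
    rep$roc <- curves$roc
    rep$pr <- curves$pr
    rep$auc <- curves$auc
    rep$average_precision <- curves$average_precision
    rep$calibration <- calibration_bins(y_true, probs, positive)
    rep$decision <- decision_curve(y_true, probs, positive)
  }
  if (boot_B > 0) {
    acc_fn <- function(yt, yp) mean(yt == yp)
    rep$ci <- list(
      acc = bootstrap_ci(acc_fn, y_true, y_pred, B = boot_B,
                         seed = derive_seed(seed, "ci_acc")))
    se_fn <- function(yt, yp) {
      cm <- confusion(yt, yp, positive)
      if (cm$tp + cm$fn == 0) NA_real_ else cm$tp / (cm$tp + cm$fn)
    }
    sp_fn <- function(yt, yp) {
      cm <- confusion(yt, yp, positive)
      if (cm$tn + cm$fp == 0) NA_real_ else cm$tn / (cm$tn + cm$fp)
    }
    rep$ci$se <- bootstrap_ci(se_fn, y_true, y_pred, B = boot_B,
                              seed = derive_seed(seed, "ci_se"))
    rep$ci$sp <- bootstrap_ci(sp_fn, y_true, y_pred, B = boot_B,
                              seed = derive_seed(seed, "ci_sp"))
    if (!is.null(probs)) {
      auc_fn <- function(yt, pr) {
        if (length(unique(yt)) < 2) return(NA_real_)
        roc_pr_curves(yt, pr, positive)$auc
      }
      rep$ci$auc <- bootstrap_ci(auc_fn, y_true, probs, B = boot_B,
                                 seed = derive_seed(seed, "ci_auc"))
    }
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  mac <- x$metrics[x$metrics$class == "macro", ]
  cat(sprintf(
    "<metric_report: n=%d acc=%.4f se=%.4f sp=%.4f f=%.4f%s>\n",
    x$n, mac$acc, mac$se, mac$sp, mac$f_scr,
    if (!is.null(x$auc)) sprintf(" auc=%.4f", x$auc) else ""))
  invisible(x)
}
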