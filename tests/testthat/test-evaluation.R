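test_that("confusion counts are exact and validated", {
  yt <- rep(c("pos", "neg"), each = 5)
  cm <- confusion(yt, yt, "pos")
  expect_equal(c(cm$tp, cm$tn, cm$fp, cm$fn), c(5, 5, 0, 0))
  inv <- confusion(yt, rev(yt), "pos")
  expect_equal(c(inv$tp, inv$tn, inv$fp, inv$fn), c(0, 0, 5, 5))
  # brute-force pairwise count on random vectors
  set.seed(31)
  for (i in 1:20) {
    a <- sample(c("x", "y"), 30, replace = TRUE)
    b <- sample(c("x", "y"), 30, replace = TRUE)
    cm2 <- confusion(a, b, "x")
    expect_equal(cm2$tp, sum(a == "x" & b == "x"))
    expect_equal(cm2$fn, sum(a == "x" & b == "y"))
    expect_equal(cm2$fp, sum(a == "y" & b == "x"))
    expect_equal(cm2$tn, sum(a == "y" & b == "y"))
  }
  expect_error(confusion(yt, yt, "unknown"), class = "ctrender_label_error")
  expect_error(confusion(yt, rep("weird", 10), "pos"),
               class = "ctrender_label_error")
})

brute_metrics <- function(tp, tn, fp, fn) {
  c(se = tp / (fn + tp), sp = tn / (fp + tn), pre = tp / (fp + tp),
    f_scr = 2 * tp / (2 * tp + fn + fp),
    acc = (tn + tp) / (tn + tp + fn + fp))
}

test_that("macro metrics agree with the formula oracle on random matrices", {
  # direct evaluation example
  cm <- structure(list(tp = 3, fn = 1, fp = 0, tn = 4, positive = "pos"),
                  class = "ct_confusion")
  m <- macro_metrics(list(cm))
  row <- m[m$class == "pos", ]
  expect_equal(row$se, 0.75)
  expect_equal(row$sp, 1)
  expect_equal(row$pre, 1)
  expect_equal(row$f_scr, 6 / 7, tolerance = 1e-12)
  expect_equal(row$acc, 0.875)
  # perfect predictions
  perf <- structure(list(tp = 7, fn = 0, fp = 0, tn = 7, positive = "p"),
                    class = "ct_confusion")
  mp <- macro_metrics(list(perf))
  expect_true(all(mp[mp$class == "macro", -1] == 1))
  # 100 random confusion matrices against an independent implementation
  set.seed(32)
  for (i in 1:100) {
    counts <- rpois(4, 20) + 1
    cm1 <- structure(list(tp = counts[1], tn = counts[2], fp = counts[3],
                          fn = counts[4], positive = "A"),
                     class = "ct_confusion")
    cm2 <- structure(list(tp = counts[2], tn = counts[1], fp = counts[4],
                          fn = counts[3], positive = "B"),
                     class = "ct_confusion")
    got <- macro_metrics(list(cm1, cm2))
    e1 <- brute_metrics(counts[1], counts[2], counts[3], counts[4])
    e2 <- brute_metrics(counts[2], counts[1], counts[4], counts[3])
    mac <- got[got$class == "macro", ]
    for (nm in names(e1)) {
      expect_equal(mac[[nm]], unname((e1[nm] + e2[nm]) / 2),
                   tolerance = 1e-12)
    }
  }
  # class-symmetric matrix: macro equals per-class values
  sym <- structure(list(tp = 4, tn = 4, fp = 2, fn = 2, positive = "A"),
                   class = "ct_confusion")
  sym2 <- structure(list(tp = 4, tn = 4, fp = 2, fn = 2, positive = "B"),
                    class = "ct_confusion")
  ms <- macro_metrics(list(sym, sym2))
  expect_equal(unlist(ms[ms$class == "macro", -1]),
               unlist(ms[ms$class == "A", -1]))
  # zero denominators warn and yield 0
  degen <- structure(list(tp = 0, tn = 5, fp = 0, fn = 0, positive = "A"),
                     class = "ct_confusion")
  ws <- testthat::capture_warnings(md <- macro_metrics(list(degen)))
  expect_true(any(grepl("Zero denominator", ws)))
  expect_equal(md$se[1], 0)
  expect_equal(md$pre[1], 0)
})

test_that("grouped splits never leak patients and partition cleanly", {
  coh <- generate_cohort(cohort_config(n_patients_per_class = 10,
                                       image_size = 32, seed = 33))
  sp <- grouped_split(coh, "holdout", ratio = 0.7, seed = 1)
  pat_of <- function(ids) unique(coh$patient_id[coh$image_id %in% ids])
  expect_length(intersect(pat_of(sp$train_ids), pat_of(sp$test_ids)), 0)
  # 7 train + 3 test patients per class
  tr_pat <- dplyr::distinct(coh[coh$image_id %in% sp$train_ids, ],
                            patient_id, label)
  expect_equal(as.integer(table(tr_pat$label)), c(7L, 7L))
  expect_setequal(c(sp$train_ids, sp$test_ids), coh$image_id)
  # k-fold: 2 patients per class per fold, folds partition the cohort
  kf <- grouped_split(coh, "kfold", k = 5, seed = 2)
  expect_length(kf$folds, 5)
  expect_setequal(unlist(kf$folds), coh$image_id)
  for (f in kf$folds) {
    fp <- dplyr::distinct(coh[coh$image_id %in% f, ], patient_id, label)
    expect_equal(as.integer(table(fp$label)), c(2L, 2L))
  }
  # determinism
  expect_identical(grouped_split(coh, "kfold", k = 5, seed = 2)$folds,
                   kf$folds)
  expect_error(grouped_split(coh, "kfold", k = 12),
               class = "ctrender_split_error")
})

test_that("ROC/PR agree with the concordant-pair oracle and handle ties", {
  y <- rep(c("p", "n"), each = 10)
  perfect <- c(rnorm(10, 5), rnorm(10, -5))
  expect_equal(roc_pr_curves(y, perfect, "p")$auc, 1)
  expect_equal(roc_pr_curves(y, rep(0.5, 20), "p")$auc, 0.5)
  set.seed(34)
  for (i in 1:10) {
    scores <- round(rnorm(20), 1)   # rounding forces occasional ties
    res <- roc_pr_curves(y, scores, "p")
    pos <- scores[y == "p"]; neg <- scores[y == "n"]
    pairs <- outer(pos, neg, `-`)
    mw <- (sum(pairs > 0) + 0.5 * sum(pairs == 0)) / length(pairs)
    expect_equal(res$auc, mw, tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(pROC::roc(y, scores, levels = c("n", "p"),
                                                  direction = "<")))
      expect_equal(res$auc, as.numeric(ref), tolerance = 1e-12)
    }
  }
  expect_error(roc_pr_curves(rep("p", 5), rnorm(5), "p"),
               class = "ctrender_label_error")
})

test_that("calibration bins match a brute-force binning oracle", {
  y <- rep(c("p", "n"), 25)
  cal <- calibration_bins(y, rep(0.5, 50), "p")
  occ <- cal[!cal$empty, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$mean_pred - occ$obs_freq, 0)
  # probabilities equal to outcomes: end bins have zero gap
  y01 <- c(rep("p", 5), rep("n", 5))
  cal2 <- calibration_bins(y01, c(rep(1, 5), rep(0, 5)), "p")
  occ2 <- cal2[!cal2$empty, ]
  expect_equal(occ2$mean_pred, occ2$obs_freq)
  # random draws against independent bin means
  set.seed(35)
  pr <- runif(200)
  yy <- ifelse(rbinom(200, 1, pr) == 1, "p", "n")
  cal3 <- calibration_bins(yy, pr, "p")
  for (b in 1:10) {
    idx <- pr >= (b - 1) / 10 & (pr < b / 10 | (b == 10 & pr <= 1))
    if (any(idx)) {
      expect_equal(cal3$mean_pred[b], mean(pr[idx]))
      expect_equal(cal3$obs_freq[b], mean(yy[idx] == "p"))
      expect_equal(cal3$n[b], sum(idx))
    } else {
      expect_true(cal3$empty[b])
    }
  }
  expect_error(calibration_bins(yy, pr * 2, "p"),
               class = "ctrender_prob_error")
})

test_that("decision curve reproduces the net-benefit formula", {
  # treat-none is identically zero
  y <- rep(c("p", "n"), each = 50)
  dc <- decision_curve(y, runif(100), "p")
  expect_true(all(dc$treat_none == 0))
  # all predicted positive at prevalence 0.5 and pt = 0.5 -> NB = 0
  dc2 <- decision_curve(y, rep(1, 100), "p", thresholds = 0.5)
  expect_equal(dc2$net_benefit, 0)
  expect_equal(dc2$treat_all, 0)
  # direct formula: TP=50, FP=10, N=100, pt=0.1
  probs <- c(rep(0.9, 50), rep(0.9, 10), rep(0.05, 40))
  dc3 <- decision_curve(y, probs, "p", thresholds = 0.1)
  expect_equal(dc3$net_benefit, 0.5 - 0.1 * (0.1 / 0.9), tolerance = 1e-12)
  expect_warning(decision_curve(y, probs, "p", thresholds = c(0, 0.5)),
                 "excluded")
})

test_that("bootstrap intervals are seeded, degenerate-safe and calibrated", {
  y <- rep(c("p", "n"), each = 20)
  pred <- y
  ci1 <- bootstrap_ci(function(a, b) mean(a == b), y, pred, B = 200, seed = 5)
  expect_equal(ci1$lower, ci1$upper)   # constant metric -> zero width
  expect_equal(ci1$estimate, 1)
  ci2 <- bootstrap_ci(function(a, b) mean(a == b), y, pred, B = 200, seed = 5)
  expect_identical(ci1, ci2)
  # coverage of the true accuracy of a Bernoulli(0.8) predictor
  set.seed(36)
  n <- 200
  cover <- vapply(1:150, function(r) {
    yt <- sample(c("p", "n"), n, replace = TRUE)
    correct <- rbinom(n, 1, 0.8) == 1
    yp <- ifelse(correct, yt, ifelse(yt == "p", "n", "p"))
    ci <- bootstrap_ci(function(a, b) mean(a == b), yt, yp, B = 200,
                       seed = r)
    ci$lower <= 0.8 && 0.8 <= ci$upper
  }, logical(1))
  expect_gte(mean(cover), 0.88)
})

test_that("metric_report bundles metrics, curves and CIs coherently", {
  set.seed(37)
  y <- rep(c("mesothelioma", "non_mesothelioma"), each = 30)
  probs <- pmin(pmax(ifelse(y == "mesothelioma", 0.8, 0.2) + rnorm(60, 0, 0.15), 0), 1)
  pred <- ifelse(probs > 0.5, "mesothelioma", "non_mesothelioma")
  rep <- metric_report(y, pred, probs, boot_B = 100)
  expect_s3_class(rep, "metric_report")
  g <- glance(rep)
  expect_true(all(unlist(g[, c("acc", "se", "sp", "pre", "f_scr")]) >= 0 &
                    unlist(g[, c("acc", "se", "sp", "pre", "f_scr")]) <= 1))
  expect_true(g$auc > 0.5)
  ti <- tidy(rep)
  expect_true(all(c("class", "metric", "value") %in% names(ti)))
  expect_true(any(!is.na(ti$conf_low)))
  # CIs bracket their estimates
  for (nm in names(rep$ci)) {
    expect_lte(rep$ci[[nm]]$lower, rep$ci[[nm]]$estimate)
    expect_gte(rep$ci[[nm]]$upper, rep$ci[[nm]]$estimate)
  }
  # plots build without error
  for (w in c("roc", "pr", "calibration", "decision", "confusion")) {
    expect_s3_class(autoplot(rep, which = w), "ggplot")
  }
})
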