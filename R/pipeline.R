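#' Pipeline configuration
#'
#' Single configuration object for the full three-step pipeline: cohort (or
#' input directory), backbone hyperparameters, renderer settings, selection
#' and classifier modes, split scheme and output contract. One global seed
#' fans out to per-stage derived seeds (see [derive_seed()]) so stages can
#' be rerun independently.
#'
#' @param cohort A [cohort_config()], or `NULL` when `input_dir` is given.
#' @param input_dir Optional directory with a previously written cohort
#'   (see [write_cohort()]).
#' @param backbone A [backbone_spec()].
#' @param renderer List of renderer settings: `H`, `W`, and per-kind epochs.
#' @param selection `"ds"` (discriminative score) or `"variance"`.
#' @param classifier `"residual_svm"`, `"logreg"` or `"direct_logits"`.
#' @param split List with holdout `ratio` and cross-validation `k`.
#' @param extractor List with residual-extractor `epochs`.
#' @param boot_B Bootstrap resamples for confidence intervals.
#' @param seed Global integer seed.
#' @param out_dir Optional output directory for persisted artifacts.
#' @param write_images Whether to persist PNGs of rendered/selected images
#'   (tables and reports are always persisted when `out_dir` is set).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            input_dir = NULL,
                            backbone = backbone_spec(),
                            renderer = list(H = 32, W = 32,
                                            decoder_epochs = 300,
                                            gan_epochs = 150,
                                            nerv_epochs = 150),
                            selection = c("ds", "variance"),
                            classifier = c("residual_svm", "logreg",
                                           "direct_logits"),
                            split = list(ratio = 0.7, k = 5),
                            extractor = list(epochs = 4),
                            boot_B = 200,
                            seed = 42,
                            out_dir = NULL,
                            write_images = FALSE) {
  selection <- match.arg(selection)
  classifier <- match.arg(classifier)
  if (is.null(input_dir)) stopifnot(inherits(cohort, "cohort_config"))
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop_ctrender(sprintf("`input_dir` '%s' does not exist.", input_dir),
                  class = "ctrender_config_error")
  }
  structure(list(cohort = cohort, input_dir = input_dir, backbone = backbone,
                 renderer = renderer, selection = selection,
                 classifier = classifier, split = split,
                 extractor = extractor, boot_B = boot_B,
                 seed = as.integer(seed), out_dir = out_dir,
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

run_stage <- function(run_env, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "ctrender_stage_error")
  })
  run_env$timings[[name]] <- as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs"))
  res
}

# Shared upstream artifacts: cohort -> overlay -> split -> backbone ->
# class features -> (optionally) renderers + candidates + centroids.
build_pipeline_context <- function(config, need_render = TRUE) {
  run_env <- new.env()
  run_env$timings <- list()
  seed <- config$seed
  images <- run_stage(run_env, "cohort", {
    if (!is.null(config$input_dir)) read_cohort(config$input_dir)
    else generate_cohort(config$cohort)
  })
  images <- run_stage(run_env, "segment_overlay", segment_overlay_cohort(images))
  split <- run_stage(run_env, "split", {
    grouped_split(images, "holdout", ratio = config$split$ratio,
                  seed = derive_seed(seed, "holdout"))
  })
  cv_split <- run_stage(run_env, "cv_split", {
    grouped_split(images, "kfold", k = config$split$k,
                  seed = derive_seed(seed, "kfold"))
  })
  backbone <- run_stage(run_env, "backbone", {
    spec <- config$backbone
    spec$seed <- derive_seed(seed, "backbone")
    train_backbone(images, spec, split$train_ids)
  })
  features <- run_stage(run_env, "class_features",
                        extract_class_features(backbone, images))
  ctx <- list(images = images, split = split, cv_split = cv_split,
              backbone = backbone, features = features,
              timings = run_env$timings, config = config,
              cache = new.env(parent = emptyenv()))
  if (need_render) {
    tr_feat <- features[features$image_id %in% split$train_ids, ]
    H <- config$renderer$H
    W <- config$renderer$W
    renderers <- run_stage(run_env, "renderers", list(
      train_decoder_renderer(tr_feat, H, W, seed = derive_seed(seed, "decoder"),
                             epochs = config$renderer$decoder_epochs),
      train_gan_renderer(tr_feat, H, W, seed = derive_seed(seed, "gan"),
                         epochs = config$renderer$gan_epochs),
      train_nerv_renderer(tr_feat, H, W, seed = derive_seed(seed, "nerv"),
                          epochs = config$renderer$nerv_epochs)))
    candidates <- run_stage(run_env, "render", render_all(features, renderers))
    centroids <- run_stage(run_env, "centroids",
                           fit_centroids(candidates, split$train_ids))
    ctx$renderers <- renderers
    ctx$candidates <- candidates
    ctx$centroids <- centroids
  }
  ctx$timings <- run_env$timings
  ctx
}

select_candidates <- function(ctx, selection) {
  if (selection == "ds") {
    select_representatives(ctx$candidates, ctx$centroids)
  } else {
    variance_select(ctx$candidates)
  }
}

# Features for the classification stage, given a training id set.
# Image pathway: train the residual extractor on the training split's
# selected images, then embed everything. Direct-logits: raw logits.
# Extractor features depend only on (selection manifest, training ids), so
# they are cached per split within a pipeline context: scenarios that share
# a manifest (e.g. SVM vs logistic regression on DS-selected images) reuse
# the same embedding rather than retraining the extractor.
stage_features <- function(ctx, manifest, classifier, train_ids, seed,
                           cache_key = NULL) {
  if (classifier == "direct_logits") {
    X <- direct_logit_features(ctx$features)
    rownames(X) <- ctx$features$image_id
    return(list(X = X, ids = ctx$features$image_id,
                labels = ctx$features$label))
  }
  if (!is.null(cache_key) && !is.null(ctx$cache) &&
      !is.null(ctx$cache[[cache_key]])) {
    return(ctx$cache[[cache_key]])
  }
  extractor <- train_residual_extractor(
    manifest, train_ids, epochs = ctx$config$extractor$epochs,
    seed = derive_seed(seed, "extractor"))
  feats <- extract_residual_features(manifest, extractor)
  X <- as.matrix(feats[, grep("^R", names(feats))])
  rownames(X) <- manifest$image_id
  out <- list(X = X, ids = manifest$image_id, labels = manifest$label,
              extractor = extractor)
  if (!is.null(cache_key) && !is.null(ctx$cache)) {
    ctx$cache[[cache_key]] <- out
  }
  out
}

fit_stage_classifier <- function(X, labels, classifier, seed) {
  if (classifier == "logreg") train_logreg(X, labels)
  else train_svm(X, labels, seed = seed)
}

# Holdout + k-fold evaluation of one scenario on shared upstream artifacts.
evaluate_scenario <- function(ctx, selection, classifier, seed,
                              boot_B = NULL) {
  config <- ctx$config
  boot_B <- boot_B %||% config$boot_B
  manifest <- if (classifier == "direct_logits") NULL
              else select_candidates(ctx, selection)
  split <- ctx$split
  # extractor seeds derive from the shared config seed and the split, not
  # the scenario, so cached embeddings are scenario-independent
  ex_seed <- function(tag) derive_seed(config$seed, paste0("stagefeat_", tag))
  # ---- holdout ----
  sf <- stage_features(ctx, manifest, classifier, split$train_ids,
                       ex_seed(paste0(selection, "_holdout")),
                       cache_key = paste0(selection, "_holdout"))
  tr <- sf$ids %in% split$train_ids
  clf <- fit_stage_classifier(sf$X[tr, , drop = FALSE], sf$labels[tr],
                              classifier, derive_seed(seed, "svm_holdout"))
  te <- !tr
  pred <- predict(clf, sf$X[te, , drop = FALSE])
  probs <- predict(clf, sf$X[te, , drop = FALSE], type = "prob")
  holdout <- metric_report(sf$labels[te], pred,
                           probs = probs[, "mesothelioma"],
                           boot_B = boot_B, seed = derive_seed(seed, "ho_ci"))
  # ---- k-fold CV at the classification stage ----
  folds <- ctx$cv_split$folds
  all_true <- character(0)
  all_pred <- character(0)
  all_prob <- numeric(0)
  fold_cms <- list()
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(sf$ids, test_ids)
    sff <- stage_features(ctx, manifest, classifier, train_ids,
                          ex_seed(paste0(selection, "_fold", f)),
                          cache_key = paste0(selection, "_fold", f))
    trf <- sff$ids %in% train_ids
    clff <- fit_stage_classifier(sff$X[trf, , drop = FALSE], sff$labels[trf],
                                 classifier,
                                 derive_seed(seed, paste0("svm_fold", f)))
    tef <- !trf
    predf <- predict(clff, sff$X[tef, , drop = FALSE])
    probf <- predict(clff, sff$X[tef, , drop = FALSE], type = "prob")
    all_true <- c(all_true, sff$labels[tef])
    all_pred <- c(all_pred, predf)
    all_prob <- c(all_prob, probf[, "mesothelioma"])
    fold_cms[[f]] <- confusion(sff$labels[tef], predf, "mesothelioma")
  }
  cv <- metric_report(all_true, all_pred, probs = all_prob, boot_B = boot_B,
                      seed = derive_seed(seed, "cv_ci"))
  cv$fold_confusions <- fold_cms
  list(holdout = holdout, cv = cv, manifest = manifest,
       extractor = sf$extractor, classifier = clf)
}

#' Run the full hybrid pipeline
#'
#' Executes segment, train backbone, extract class features, render, select
#' and classify on one configuration, and evaluates the classification stage
#' under both the patient-grouped 70/30 holdout and k-fold cross-validation.
#' When `classifier = "direct_logits"` the rendering and selection stages
#' are skipped and the backbone's raw logits feed the SVM. Deterministic
#' given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run`: the shared artifacts (`images`, `split`,
#'   `backbone`, `features`, `candidates`, `manifest`), a `reports` list
#'   with `holdout` and `cv` [metric_report()]s, per-stage `timings`, and
#'   the configuration.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need_render <- config$classifier != "direct_logits"
  ctx <- build_pipeline_context(config, need_render = need_render)
  res <- evaluate_scenario(ctx, config$selection, config$classifier,
                           derive_seed(config$seed, "classify"))
  run <- structure(list(config = config, images = ctx$images,
                        split = ctx$split, cv_split = ctx$cv_split,
                        backbone = ctx$backbone, features = ctx$features,
                        candidates = ctx$candidates,
                        centroids = ctx$centroids,
                        manifest = res$manifest,
                        extractor = res$extractor,
                        classifier = res$classifier,
                        reports = list(holdout = res$holdout, cv = res$cv),
                        timings = ctx$timings),
                   class = "pipeline_run")
  if (!is.null(config$out_dir)) persist_run(run, config$out_dir)
  run
}

#' Run the ablation grid
#'
#' Evaluates the four pipeline scenarios (full model; no rendering with
#' direct logits into the SVM; variance-threshold selection instead of the
#' discriminative score; logistic regression instead of the SVM) under both
#' holdout and k-fold schemes, sharing the upstream cohort, backbone,
#' features and rendered candidates so the comparison isolates the ablated
#' component.
#'
#' @param config A [pipeline_config()] (its `selection`/`classifier` fields
#'   are ignored; the grid fixes them per scenario).
#' @return A tibble with one row per scenario and scheme: `scenario`,
#'   `scheme`, `acc`, `se`, `sp`, `pre`, `f_scr`, `auc`.
#' @export
run_ablation_grid <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ctx <- build_pipeline_context(config, need_render = TRUE)
  scenarios <- list(
    full = list(selection = "ds", classifier = "residual_svm"),
    no_rendering = list(selection = "ds", classifier = "direct_logits"),
    variance_selector = list(selection = "variance",
                             classifier = "residual_svm"),
    logistic_regression = list(selection = "ds", classifier = "logreg"))
  rows <- list()
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    res <- evaluate_scenario(ctx, sc$selection, sc$classifier,
                             derive_seed(config$seed, paste0("grid_", nm)),
                             boot_B = 0)
    for (scheme in c("holdout", "cv")) {
      rep <- res[[scheme]]
      mac <- rep$metrics[rep$metrics$class == "macro", ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = nm, scheme = scheme, acc = mac$acc, se = mac$se,
        sp = mac$sp, pre = mac$pre, f_scr = mac$f_scr,
        auc = rep$auc %||% NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "context") <- ctx
  out
}

#' Accuracy of each single-renderer pathway
#'
#' Diagnostic companion to the ablation grid: classify using only one
#' renderer's candidates (no selection step), for each of the three kinds.
#' Holdout scheme only.
#'
#' @param ctx A pipeline context, e.g. `attr(run_ablation_grid(cfg),
#'   "context")`.
#' @return A tibble: `renderer`, `acc`.
#' @export
single_renderer_accuracy <- function(ctx) {
  split <- ctx$split
  purrr::map_dfr(candidate_kinds(), function(k) {
    manifest <- build_manifest(ctx$candidates, rep(k, nrow(ctx$candidates)), "")
    sf <- stage_features(ctx, manifest, "residual_svm", split$train_ids,
                         derive_seed(ctx$config$seed, paste0("single_", k)))
    tr <- sf$ids %in% split$train_ids
    clf <- fit_stage_classifier(sf$X[tr, , drop = FALSE], sf$labels[tr],
                                "residual_svm",
                                derive_seed(ctx$config$seed, paste0("svm_", k)))
    pred <- predict(clf, sf$X[!tr, , drop = FALSE])
    tibble::tibble(renderer = k, acc = mean(pred == sf$labels[!tr]))
  })
}

#' @export
print.pipeline_run <- function(x, ...) {
  mac_h <- x$reports$holdout$metrics
  mac_h <- mac_h[mac_h$class == "macro", ]
  mac_c <- x$reports$cv$metrics
  mac_c <- mac_c[mac_c$class == "macro", ]
  cat(sprintf(
    "<pipeline_run: %d images, %s/%s; holdout acc=%.4f, cv acc=%.4f>\n",
    nrow(x$images), x$config$selection, x$config$classifier, mac_h$acc,
    mac_c$acc))
  invisible(x)
}
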