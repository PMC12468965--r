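#' SVM specification (cubic kernel, MATLAB-style conventions)
#'
#' Polynomial kernel of degree 3 ("Cubic"), automatic kernel scale
#' `gamma = 1 / (d * mean feature variance)`, box constraint 1, one-vs-one
#' multiclass, and Platt-scaled probability outputs so downstream
#' calibration and decision-curve analysis have probabilities to work with.
#'
#' @param degree Polynomial degree.
#' @param cost Box constraint.
#' @param coef0 Kernel offset.
#' @return An `svm_spec` object.
#' @export
svm_spec <- function(degree = 3, cost = 1, coef0 = 1) {
  structure(list(kernel = "polynomial", degree = degree, cost = cost,
                 coef0 = coef0, kernel_scale = "auto",
                 multiclass = "one_vs_one", probability = "platt"),
            class = "svm_spec")
}

as_feature_matrix <- function(features) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop_ctrender("Features must be finite.")
  X
}

check_labels <- function(labels) {
  labels <- factor(as.character(labels), levels = class_levels(labels))
  if (nlevels(labels) < 2) {
    stop_ctrender("Need at least 2 classes to train a classifier.",
                  class = "ctrender_label_error")
  }
  labels
}

#' Train a cubic-kernel SVM
#'
#' @param features Data frame or matrix of numeric features (rows are
#'   samples).
#' @param labels Class labels.
#' @param spec An [svm_spec()].
#' @param seed Seed for the internal Platt-calibration folds.
#' @return A `ctrender_classifier` exposing hard labels, decision scores
#'   and calibrated probabilities through [predict.ctrender_classifier()].
#' @export
train_svm <- function(features, labels, spec = svm_spec(), seed = 42) {
  X <- as_feature_matrix(features)
  y <- check_labels(labels)
  mv <- mean(apply(X, 2, var))
  gamma <- if (is.finite(mv) && mv > 1e-12) 1 / (ncol(X) * mv) else 1 / ncol(X)
  fit <- local_seed(seed, {
    e1071::svm(X, y, kernel = "polynomial", degree = spec$degree,
               gamma = gamma, coef0 = spec$coef0, cost = spec$cost,
               probability = TRUE, scale = FALSE)
  })
  structure(list(kind = "svm", fit = fit, classes = levels(y), spec = spec,
                 gamma = gamma),
            class = "ctrender_classifier")
}

#' Train an L2-regularized logistic regression
#'
#' Linear baseline with the same prediction interface as [train_svm()].
#' Ridge regularization (small lambda) keeps coefficients finite even on
#' perfectly separable data.
#'
#' @inheritParams train_svm
#' @param lambda Ridge penalty.
#' @return A `ctrender_classifier`.
#' @export
train_logreg <- function(features, labels, lambda = 1e-3) {
  X <- as_feature_matrix(features)
  y <- check_labels(labels)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(kind = "logreg", fit = fit, classes = levels(y),
                 lambda = lambda),
            class = "ctrender_classifier")
}

#' Predict from a trained classifier
#'
#' @param object A `ctrender_classifier`.
#' @param newdata Feature data frame or matrix.
#' @param type `"class"` for hard labels, `"prob"` for a matrix of class
#'   probabilities (columns named by class), `"score"` for the decision
#'   value / linear predictor oriented so larger means the first class.
#' @param ... Unused.
#' @export
predict.ctrender_classifier <- function(object, newdata,
                                        type = c("class", "prob", "score"),
                                        ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (object$kind == "svm") {
    pr <- predict(object$fit, X, probability = TRUE, decision.values = TRUE)
    probs <- attr(pr, "probabilities")[, object$classes, drop = FALSE]
    if (type == "class") return(as.character(pr))
    if (type == "prob") return(probs)
    return(probs[, 1])
  }
  # glmnet binomial: response = P(second level)
  p2 <- as.numeric(predict(object$fit, X, type = "response"))
  probs <- cbind(1 - p2, p2)
  colnames(probs) <- object$classes
  if (type == "class") {
    return(object$classes[ifelse(p2 > 0.5, 2L, 1L)])
  }
  if (type == "prob") return(probs)
  probs[, 1]
}

#' Train an SVM directly on class-based logit features
#'
#' Ablation pathway that bypasses the rendering stage entirely: the raw
#' pre-softmax logits of the backbone feed the cubic-kernel SVM.
#'
#' @param feature_table Feature tibble with `logit1..logitK` columns (falls
#'   back to `F1..FK` when raw logits are absent).
#' @param labels Class labels (defaults to `feature_table$label`).
#' @param spec An [svm_spec()].
#' @param seed Seed for Platt calibration.
#' @return A `ctrender_classifier`.
#' @export
classify_direct_logits <- function(feature_table, labels = NULL,
                                   spec = svm_spec(), seed = 42) {
  labels <- labels %||% feature_table$label
  X <- direct_logit_features(feature_table)
  train_svm(X, labels, spec, seed = seed)
}

direct_logit_features <- function(feature_table) {
  cols <- grep("^logit[0-9]+$", names(feature_table), value = TRUE)
  if (length(cols) == 0) {
    cols <- grep("^F[0-9]+$", names(feature_table), value = TRUE)
  }
  if (length(cols) == 0) {
    stop_ctrender("Feature table has no logit or F columns.")
  }
  as.matrix(feature_table[, cols])
}

# ---- residual feature extractor -------------------------------------------

res_net_init <- function(K, seed) {
  local_seed(seed, {
    list(W0 = he_init(9, 16, 9), b0 = numeric(16),
         Wr1a = he_init(9 * 16, 16, 9 * 16), br1a = numeric(16),
         Wr1b = he_init(9 * 16, 16, 9 * 16), br1b = numeric(16),
         W1 = he_init(9 * 16, 32, 9 * 16), b1 = numeric(32),
         Wr2a = he_init(9 * 32, 32, 9 * 32), br2a = numeric(32),
         Wr2b = he_init(9 * 32, 32, 9 * 32), br2b = numeric(32),
         Wd = he_init(32, K, 32), bd = numeric(K))
  })
}

res_block_fw <- function(X, Wa, ba, Wb, bb) {
  ca <- conv_fw(X, Wa, ba, 3, 1, 1)
  aa <- relu_fw(ca$out)
  cb <- conv_fw(aa, Wb, bb, 3, 1, 1)
  s <- X + cb$out
  list(out = relu_fw(s), ca = ca, aa = aa, cb = cb, s = s, X = X)
}

res_block_bw <- function(cache, Wa, Wb, dOut) {
  dS <- relu_bw(cache$s, dOut)
  gb <- conv_bw(cache$cb, Wb, dS)
  dAa <- relu_bw(cache$ca$out, gb$dX)
  ga <- conv_bw(cache$ca, Wa, dAa)
  list(dX = dS + ga$dX, dWa = ga$dW, dba = ga$db, dWb = gb$dW, dbb = gb$db)
}

res_net_fw <- function(params, X, keep_cache = TRUE) {
  c0 <- conv_fw(X, params$W0, params$b0, 3, 2, 1)
  a0 <- relu_fw(c0$out)
  r1 <- res_block_fw(a0, params$Wr1a, params$br1a, params$Wr1b, params$br1b)
  c1 <- conv_fw(r1$out, params$W1, params$b1, 3, 2, 1)
  a1 <- relu_fw(c1$out)
  r2 <- res_block_fw(a1, params$Wr2a, params$br2a, params$Wr2b, params$br2b)
  g <- gap_fw(r2$out)
  logits <- dense_fw(g, params$Wd, params$bd)
  out <- list(logits = logits, fc = g)
  if (keep_cache) out$cache <- list(c0 = c0, a0 = a0, r1 = r1, c1 = c1,
                                    a1 = a1, r2 = r2, g = g)
  out
}

res_net_bw <- function(params, cache, dlogits) {
  gd <- dense_bw(cache$g, params$Wd, dlogits)
  dg <- gap_bw(gd$dX, dim(cache$r2$out))
  b2 <- res_block_bw(cache$r2, params$Wr2a, params$Wr2b, dg)
  d1 <- relu_bw(cache$c1$out, b2$dX)
  g1 <- conv_bw(cache$c1, params$W1, d1)
  b1 <- res_block_bw(cache$r1, params$Wr1a, params$Wr1b, g1$dX)
  d0 <- relu_bw(cache$c0$out, b1$dX)
  g0 <- conv_bw(cache$c0, params$W0, d0)
  list(W0 = g0$dW, b0 = g0$db,
       Wr1a = b1$dWa, br1a = b1$dba, Wr1b = b1$dWb, br1b = b1$dbb,
       W1 = g1$dW, b1 = g1$db,
       Wr2a = b2$dWa, br2a = b2$dba, Wr2b = b2$dWb, br2b = b2$dbb,
       Wd = gd$dW, bd = gd$db)
}

stack_renders <- function(imgs, S = 32L) {
  X <- array(0, c(S, S, 1, length(imgs)))
  for (b in seq_along(imgs)) {
    im <- imgs[[b]]
    if (nrow(im) != S || ncol(im) != S) {
      im <- as.matrix(EBImage::resize(EBImage::Image((im + 1) / 2), w = S,
                                      h = S)) * 2 - 1
    }
    X[, , 1, b] <- im
  }
  X
}

#' Train the small residual feature extractor
#'
#' A 2-residual-block CNN trained briefly as a classifier on the selected
#' representative images of the training split; its global-average-pooled
#' penultimate layer (declared width 32) is the feature map the SVM
#' consumes. An adapter backed by a pretrained 512-wide residual network can
#' implement the same contract but requires an external weight download.
#'
#' @param selected Selection manifest tibble (with `pixels` and `label`).
#' @param train_ids Image ids of the training split.
#' @param epochs,lr,batch_size Training-loop settings.
#' @param seed Integer seed.
#' @return A `ctrender_extractor`.
#' @export
train_residual_extractor <- function(selected, train_ids = NULL, epochs = 4,
                                     lr = 1e-3, batch_size = 32, seed = 42) {
  stopifnot(is.data.frame(selected), all(c("pixels", "label") %in% names(selected)))
  if (is.null(train_ids)) train_ids <- selected$image_id
  tr <- selected[selected$image_id %in% train_ids, ]
  classes <- class_levels(tr$label)
  if (length(classes) < 2) {
    stop_ctrender("Training split must contain both classes.",
                  class = "ctrender_label_error")
  }
  y <- match(as.character(tr$label), classes)
  K <- length(classes)
  params <- res_net_init(K, seed)
  state <- adam_init(params)
  n <- nrow(tr)
  local_seed(derive_seed(seed, "residual_train"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        bidx <- ord[start:min(start + batch_size - 1L, n)]
        X <- stack_renders(tr$pixels[bidx])
        Y1h <- matrix(0, length(bidx), K)
        Y1h[cbind(seq_along(bidx), y[bidx])] <- 1
        fwd <- res_net_fw(params, X)
        ce <- softmax_ce(fwd$logits, Y1h)
        grads <- res_net_bw(params, fwd$cache, ce$dlogits)
        upd <- adam_step(params, grads, state, lr)
        params <- upd$params
        state <- upd$state
      }
    }
  })
  structure(list(params = params, classes = classes, width = 32L,
                 input_size = 32L, seed = seed),
            class = "ctrender_extractor")
}

#' Extract residual-CNN features
#'
#' Deterministic (evaluation-mode) penultimate features, one fixed-width
#' vector per image; inputs are bilinearly rescaled to the extractor's
#' input size when needed.
#'
#' @param images Tibble with a `pixels` list-column of `[-1, 1]` matrices,
#'   or a plain list of matrices.
#' @param extractor A trained `ctrender_extractor`.
#' @return A tibble `R1..Rw` of features (plus `image_id` when available).
#' @export
extract_residual_features <- function(images, extractor) {
  if (!inherits(extractor, "ctrender_extractor")) {
    stop_ctrender("`extractor` must be a trained ctrender_extractor.",
                  class = "ctrender_extractor_error")
  }
  imgs <- if (is.data.frame(images)) images$pixels else images
  n <- length(imgs)
  fc <- matrix(0, n, extractor$width)
  batch <- 128L
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    X <- stack_renders(imgs[idx], extractor$input_size)
    fc[idx, ] <- res_net_fw(extractor$params, X, keep_cache = FALSE)$fc
  }
  out <- tibble::as_tibble(as.data.frame(fc))
  names(out) <- paste0("R", seq_len(extractor$width))
  if (is.data.frame(images) && "image_id" %in% names(images)) {
    out <- dplyr::bind_cols(tibble::tibble(image_id = images$image_id), out)
  }
  out
}
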