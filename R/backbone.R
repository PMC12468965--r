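#' Backbone training specification
#'
#' Hyperparameters of the trainable image classifier whose appended logits
#' layer supplies the class-based features. Defaults follow the study
#' protocol (cross-entropy, Adam, 15 epochs, mini-batch 32, fixed seed 42,
#' constant learning rate, no weight decay, no early stopping), except that
#' the learning rate defaults to 1e-3: the bundled reference CNN is trained
#' from scratch, where 1e-4 (appropriate when fine-tuning a pretrained
#' transformer) underfits badly within 15 epochs.
#'
#' @param name Identifier of the backbone ("ref_cnn" is the bundled one;
#'   pretrained transformer adapters can implement the same contract).
#' @param learning_rate Adam learning rate (constant).
#' @param epochs Training epochs (> 0).
#' @param batch_size Mini-batch size (> 0).
#' @param input_size Side length images are bilinearly resized to before the
#'   forward pass. The reference CNN consumes the cohort's native 128 px.
#' @param seed Fixed seed controlling initialization and batch shuffling.
#' @return A `backbone_spec` object.
#' @export
backbone_spec <- function(name = "ref_cnn",
                          learning_rate = 1e-3,
                          epochs = 15,
                          batch_size = 32,
                          input_size = 128,
                          seed = 42) {
  stopifnot(is_count(epochs), is_count(batch_size), is_count(input_size),
            learning_rate > 0)
  structure(list(name = name, loss = "cross_entropy", optimizer = "adam",
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "backbone_spec")
}

# images list -> normalized array (S, S, C, B) in [-1, 1]
stack_inputs <- function(imgs, S) {
  first <- imgs[[1]]
  C <- if (length(dim(first)) == 3) dim(first)[3] else 1L
  X <- array(0, c(S, S, C, length(imgs)))
  for (b in seq_along(imgs)) {
    im <- imgs[[b]]
    if (length(dim(im)) == 2) dim(im) <- c(dim(im), 1L)
    if (dim(im)[1] != S || dim(im)[2] != S) {
      im <- as.array(EBImage::resize(EBImage::Image(im / 255, colormode = "Grayscale"),
                                     w = S, h = S)) * 255
      if (length(dim(im)) == 2) dim(im) <- c(dim(im), 1L)
    }
    X[, , , b] <- im / 127.5 - 1
  }
  X
}

input_column <- function(images) {
  if ("overlay" %in% names(images)) "overlay" else "pixels"
}

ref_cnn_init <- function(C_in, K, seed) {
  local_seed(seed, {
    list(W1 = he_init(9 * C_in, 16, 9 * C_in), b1 = numeric(16),
         W2 = he_init(9 * 16, 32, 9 * 16), b2 = numeric(32),
         W3 = he_init(9 * 32, 64, 9 * 32), b3 = numeric(64),
         Wd = he_init(64, K, 64), bd = numeric(K))
  })
}

ref_cnn_fw <- function(params, X, keep_cache = TRUE) {
  c1 <- conv_fw(X, params$W1, params$b1, 3, 2, 1)
  a1 <- relu_fw(c1$out)
  c2 <- conv_fw(a1, params$W2, params$b2, 3, 2, 1)
  a2 <- relu_fw(c2$out)
  c3 <- conv_fw(a2, params$W3, params$b3, 3, 2, 1)
  a3 <- relu_fw(c3$out)
  g <- gap_fw(a3)                              # B x 64
  logits <- dense_fw(g, params$Wd, params$bd)  # B x K
  out <- list(logits = logits, fc = g)
  if (keep_cache) out$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                                    c3 = c3, a3 = a3, g = g, X = X)
  out
}

ref_cnn_bw <- function(params, cache, dlogits) {
  gd <- dense_bw(cache$g, params$Wd, dlogits)
  dg <- gap_bw(gd$dX, dim(cache$a3))
  d3 <- relu_bw(cache$c3$out, dg)
  g3 <- conv_bw(cache$c3, params$W3, d3)
  d2 <- relu_bw(cache$c2$out, g3$dX)
  g2 <- conv_bw(cache$c2, params$W2, d2)
  d1 <- relu_bw(cache$c1$out, g2$dX)
  g1 <- conv_bw(cache$c1, params$W1, d1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, Wd = gd$dW, bd = gd$db)
}

class_levels <- function(labels) {
  lv <- unique(as.character(labels))
  std <- cohort_classes()
  if (all(lv %in% std)) std[std %in% lv] else sort(lv)
}

#' Train the reference CNN backbone
#'
#' Trains a small convolutional classifier (three stride-2 conv blocks,
#' global average pooling, linear logits head) on the training-split images
#' with the spec's hyperparameters. The logits head is the "class-based"
#' layer: its softmax probabilities become the F1..FK features.
#'
#' @param images Cohort tibble; the `overlay` list-column is consumed when
#'   present, otherwise `pixels`.
#' @param spec A [backbone_spec()].
#' @param train_ids Image ids of the training split (must respect the
#'   patient-grouped split; see [grouped_split()]).
#' @return A `ctrender_backbone` model.
#' @export
train_backbone <- function(images, spec = backbone_spec(), train_ids = NULL) {
  stopifnot(is.data.frame(images), inherits(spec, "backbone_spec"))
  if (is.null(train_ids)) train_ids <- images$image_id
  if (!all(train_ids %in% images$image_id)) {
    stop_ctrender("Some `train_ids` are not in the cohort.",
                  class = "ctrender_id_error")
  }
  tr <- images[match(train_ids, images$image_id), ]
  classes <- class_levels(tr$label)
  if (length(classes) < 2) {
    stop_ctrender("Training set must contain at least 2 classes.",
                  class = "ctrender_label_error")
  }
  col <- input_column(tr)
  S <- spec$input_size
  first <- tr[[col]][[1]]
  C_in <- if (length(dim(first)) == 3) dim(first)[3] else 1L
  K <- length(classes)
  y <- match(as.character(tr$label), classes)
  n <- nrow(tr)
  params <- ref_cnn_init(C_in, K, spec$seed)
  state <- adam_init(params)
  local_seed(derive_seed(spec$seed, "backbone_train"), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        bidx <- ord[start:min(start + spec$batch_size - 1L, n)]
        X <- stack_inputs(tr[[col]][bidx], S)
        Y1h <- matrix(0, length(bidx), K)
        Y1h[cbind(seq_along(bidx), y[bidx])] <- 1
        fwd <- ref_cnn_fw(params, X)
        ce <- softmax_ce(fwd$logits, Y1h)
        grads <- ref_cnn_bw(params, fwd$cache, ce$dlogits)
        upd <- adam_step(params, grads, state, spec$learning_rate)
        params <- upd$params
        state <- upd$state
      }
    }
  })
  model <- structure(list(params = params, spec = spec, classes = classes,
                          C_in = C_in, fc_width = 64L, input_col = col),
                     class = "ctrender_backbone")
  pr <- predict(model, tr)
  model$train_accuracy <- mean(classes[max.col(as.matrix(pr[paste0("F", seq_len(K))]))]
                               == as.character(tr$label))
  model
}

backbone_forward <- function(model, images, batch = 64L) {
  col <- if (model$input_col %in% names(images)) model$input_col else input_column(images)
  imgs <- images[[col]]
  n <- length(imgs)
  K <- length(model$classes)
  logits <- matrix(0, n, K)
  fc <- matrix(0, n, model$fc_width)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    X <- stack_inputs(imgs[idx], model$spec$input_size)
    fwd <- ref_cnn_fw(model$params, X, keep_cache = FALSE)
    logits[idx, ] <- fwd$logits
    fc[idx, ] <- fwd$fc
  }
  list(logits = logits, fc = fc)
}

#' @export
predict.ctrender_backbone <- function(object, newdata, ...) {
  fwd <- backbone_forward(object, newdata)
  probs <- softmax_rows(fwd$logits)
  out <- tibble::as_tibble(as.data.frame(probs))
  names(out) <- paste0("F", seq_along(object$classes))
  out$image_id <- newdata$image_id
  out
}

#' Extract class-based features from the logits layer
#'
#' For every image, the softmax of the appended logits layer yields one
#' probability per class: column `F1` is the probability of the first class
#' (mesothelioma in the standard cohort), `F2` of the second, and so on.
#' Raw pre-softmax logits are kept alongside (columns `logit1..logitK`) for
#' the direct-logits ablation.
#'
#' @param model A trained `ctrender_backbone`.
#' @param images Cohort tibble.
#' @return A feature tibble: `image_id`, `label` (when available),
#'   `F1..FK`, `logit1..logitK`, plus a `backbone` provenance column.
#' @export
extract_class_features <- function(model, images) {
  stopifnot(inherits(model, "ctrender_backbone"))
  fwd <- backbone_forward(model, images)
  probs <- softmax_rows(fwd$logits)
  K <- length(model$classes)
  out <- tibble::tibble(image_id = images$image_id)
  if ("label" %in% names(images)) out$label <- images$label
  for (k in seq_len(K)) out[[paste0("F", k)]] <- probs[, k]
  for (k in seq_len(K)) out[[paste0("logit", k)]] <- fwd$logits[, k]
  out$backbone <- model$spec$name
  attr(out, "classes") <- model$classes
  out
}

#' Extract dense (pre-logits) features
#'
#' Returns the penultimate representation (global-average-pooled feature
#' maps for the reference CNN), with fixed dimensionality equal to the
#' backbone's declared width.
#'
#' @inheritParams extract_class_features
#' @return A tibble: `image_id` plus `V1..Vw` columns.
#' @export
extract_fc_features <- function(model, images) {
  stopifnot(inherits(model, "ctrender_backbone"))
  fwd <- backbone_forward(model, images)
  out <- tibble::as_tibble(as.data.frame(fwd$fc))
  names(out) <- paste0("V", seq_len(ncol(fwd$fc)))
  dplyr::bind_cols(tibble::tibble(image_id = images$image_id), out)
}

#' @export
print.ctrender_backbone <- function(x, ...) {
  cat(sprintf("<ctrender_backbone: %s, classes=%s, train_acc=%.3f>\n",
              x$spec$name, paste(x$classes, collapse = "/"),
              x$train_accuracy %||% NA_real_))
  invisible(x)
}
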