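#' Deterministic target encoding of a class-probability vector
#'
#' The three renderers are trained to reproduce this shared encoding: each
#' class k owns a Gaussian bump (sd `H/6`) at a fixed anchor, the bumps are
#' mixed with the class probabilities, and the mixture is mapped to the
#' `[-1, 1]` pixel range. For two classes the anchors sit at `(H/4, W/4)` and
#' `(3H/4, 3W/4)` (half-pixel-centered coordinates, so the pair is exactly
#' symmetric under 180-degree rotation); for K > 2 they are spaced on a
#' circle. By construction the encoding is injective in z, so class
#' information survives the rendering step.
#'
#' @param z Probability vector (entries in `[0, 1]`, summing to 1 within
#'   1e-6).
#' @param H,W Output image size in pixels.
#' @return An `H x W` matrix in `[-1, 1]`.
#' @export
target_encoding <- function(z, H = 32, W = 32) {
  validate_z(z)
  K <- length(z)
  if (K == 2) {
    anchors <- rbind(c(H / 4, W / 4), c(3 * H / 4, 3 * W / 4))
  } else {
    th <- 2 * pi * (seq_len(K) - 1) / K
    anchors <- cbind(H / 2 + H / 4 * cos(th), W / 2 + W / 4 * sin(th))
  }
  sg <- H / 6
  xs <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  ys <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)
  acc <- matrix(0, H, W)
  for (k in seq_len(K)) {
    acc <- acc + z[k] * exp(-((xs - anchors[k, 1])^2 + (ys - anchors[k, 2])^2) /
                              (2 * sg^2))
  }
  pmin(pmax(2 * acc - 1, -1), 1)
}

validate_z <- function(z) {
  if (!is.numeric(z) || any(!is.finite(z)) || any(z < -1e-9 | z > 1 + 1e-9) ||
      abs(sum(z) - 1) > 1e-6) {
    stop_ctrender("`z` must be a probability vector (entries in [0,1], sum 1).",
                  class = "ctrender_z_error")
  }
  invisible(z)
}

# targets for a matrix of z rows -> (n, H*W) matrix
target_matrix <- function(Z, H, W) {
  t(apply(Z, 1, function(z) as.numeric(target_encoding(z, H, W))))
}

#' Single decoder layer
#'
#' One fully connected layer of the decoder MLP,
#' `h = activation(W %*% h_prev + b)`: hidden layers use ReLU, the final
#' layer uses Tanh so outputs land in `(-1, 1)`.
#'
#' @param h_prev Input vector (or matrix with samples in columns).
#' @param W Weight matrix, `out x in`.
#' @param b Bias vector, length `out`.
#' @param activation One of "relu", "tanh", "linear".
#' @return Activated output with the same orientation as `h_prev`.
#' @export
decoder_layer <- function(h_prev, W, b, activation = "relu") {
  v <- is.null(dim(h_prev))
  Hm <- if (v) matrix(h_prev, ncol = 1) else h_prev
  if (ncol(W) != nrow(Hm)) {
    stop_ctrender("Shape mismatch between `W` and `h_prev`.",
                  class = "ctrender_dim_error")
  }
  Z <- W %*% Hm + b
  out <- switch(activation,
                relu = relu_fw(Z),
                tanh = tanh(Z),
                linear = Z,
                stop_ctrender("Unknown activation."))
  if (v) as.numeric(out) else out
}

#' Sinusoidal positional encoding of a time index
#'
#' `[sin(2^j * pi * t), cos(2^j * pi * t)]` for `j = 0..L_bands-1`,
#' interleaved per band; the NeRV-style renderer conditions on it.
#'
#' @param t Normalized index in `[0, 1]` (vectorized).
#' @param L_bands Number of frequency bands.
#' @return A numeric vector of length `2 * L_bands` (or a matrix with one
#'   row per element of `t`).
#' @export
positional_encode <- function(t, L_bands = 6) {
  if (any(t < 0 | t > 1)) {
    stop_ctrender("`t` must lie in [0, 1].", class = "ctrender_t_error")
  }
  out <- vapply(t, function(ti) {
    as.numeric(vapply(seq_len(L_bands) - 1, function(j) {
      c(sin(2^j * pi * ti), cos(2^j * pi * ti))
    }, numeric(2)))
  }, numeric(2 * L_bands))
  if (length(t) == 1) as.numeric(out) else t(out)
}

# Extract the F1..FK probability columns of a feature table as a matrix.
feature_z <- function(feature_table) {
  fcols <- grep("^F[0-9]+$", names(feature_table), value = TRUE)
  if (length(fcols) < 2) {
    stop_ctrender("Feature table must contain F1..FK probability columns.")
  }
  Z <- as.matrix(feature_table[, fcols])
  Z <- pmin(pmax(Z, 0), 1)
  Z / rowSums(Z)
}

# Training set for a renderer: empirical z rows (subsampled), a fixed
# uniform grid along the simplex, and seeded uniform simplex draws. The
# augmentation keeps the learned map accurate over the whole simplex even
# when a well-trained backbone pushes the empirical z towards the corners.
build_z_set <- function(Z, seed, n_sub = 200, n_rand = 100) {
  K <- ncol(Z)
  n <- nrow(Z)
  t_emp <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  local_seed(seed, {
    keep <- if (n > n_sub) sort(sample.int(n, n_sub)) else seq_len(n)
    if (K == 2) {
      g1 <- seq(0, 1, by = 0.05)
      grid <- cbind(g1, 1 - g1)
    } else {
      grid <- matrix(rexp(21 * K), ncol = K)
      grid <- grid / rowSums(grid)
    }
    rand <- matrix(rexp(n_rand * K), ncol = K)
    rand <- rand / rowSums(rand)
    list(Z = rbind(Z[keep, , drop = FALSE], grid, rand),
         t = c(t_emp[keep], runif(nrow(grid) + n_rand)))
  })
}

check_degenerate <- function(Z) {
  if (all(apply(Z, 2, function(v) diff(range(v))) < 1e-9)) {
    warn("Feature table is constant; renderer trains on augmented z only.")
  }
}

new_renderer <- function(kind, params, H, W, seed, extra = list()) {
  structure(c(list(kind = kind, params = params, H = H, W = W, seed = seed),
              extra),
            class = "ctrender_renderer")
}

#' Train the decoder-MLP renderer
#'
#' An MLP `K -> 64 -> 256 -> H*W` (ReLU hidden layers, Tanh output) trained
#' with Adam to reconstruct the target encoding of each class-probability
#' vector. Fully deterministic given `seed`.
#'
#' @param feature_table Feature tibble with `F1..FK` columns (at least 10
#'   rows).
#' @param H,W Rendered image size.
#' @param seed Integer seed.
#' @param epochs Full-batch Adam steps (<= 300 by design).
#' @param lr Learning rate.
#' @return A `ctrender_renderer` of kind "decoder".
#' @export
train_decoder_renderer <- function(feature_table, H = 32, W = 32, seed = 42,
                                   epochs = 300, lr = 1e-3) {
  Z <- feature_z(feature_table)
  if (nrow(Z) < 10) stop_ctrender("Need at least 10 training samples.")
  check_degenerate(Z)
  zs <- build_z_set(Z, derive_seed(seed, "decoder_data"))
  Tm <- target_matrix(zs$Z, H, W)
  K <- ncol(Z)
  sizes <- c(K, 64, 256, H * W)
  act <- c("relu", "relu", "tanh")
  params <- mlp_init(sizes, derive_seed(seed, "decoder_init"))
  state <- adam_init(params)
  n <- nrow(zs$Z)
  for (ep in seq_len(epochs)) {
    fwd <- mlp_fw(params, zs$Z, act)
    dOut <- 2 * (fwd$out - Tm) / (n * ncol(Tm))
    grads <- mlp_bw(params, fwd$cache, act, dOut)
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params
    state <- upd$state
  }
  new_renderer("decoder", params, H, W, seed,
               list(activations = act, K = K))
}

bce_logits <- function(s, y) {
  # numerically stable: log(1 + exp(s)) - y*s
  loss <- mean(pmax(s, 0) - y * s + log1p(exp(-abs(s))))
  dlist <- (1 / (1 + exp(-s)) - y) / length(s)
  list(loss = loss, ds = dlist)
}

#' Train the conditional GAN renderer
#'
#' A conditional generator `G(z, noise)` and discriminator `D(image, z)`
#' trained adversarially, with "real" pairs being the target encoding of
#' each z. The generator loss adds `lambda_rec` times the mean squared error
#' to the target, which anchors the adversarial game to the shared encoding;
#' inference zeroes the noise for reproducibility.
#'
#' @inheritParams train_decoder_renderer
#' @param noise_dim Generator noise dimension.
#' @param lambda_rec Weight of the reconstruction term.
#' @return A `ctrender_renderer` of kind "gan" (discriminator kept in
#'   `$disc` for diagnostics).
#' @export
train_gan_renderer <- function(feature_table, H = 32, W = 32, seed = 42,
                               epochs = 200, lr = 1e-3, noise_dim = 8,
                               lambda_rec = 100) {
  Z <- feature_z(feature_table)
  if (nrow(Z) < 10) stop_ctrender("Need at least 10 training samples.")
  check_degenerate(Z)
  zs <- build_z_set(Z, derive_seed(seed, "gan_data"))
  Tm <- target_matrix(zs$Z, H, W)
  K <- ncol(Z)
  HW <- H * W
  g_sizes <- c(K + noise_dim, 64, 256, HW)
  g_act <- c("relu", "relu", "tanh")
  d_sizes <- c(HW + K, 128, 1)
  d_act <- c("relu", "linear")
  gp <- mlp_init(g_sizes, derive_seed(seed, "gan_g"))
  dp <- mlp_init(d_sizes, derive_seed(seed, "gan_d"))
  gs <- adam_init(gp)
  ds <- adam_init(dp)
  n <- nrow(zs$Z)
  local_seed(derive_seed(seed, "gan_train"), {
    for (ep in seq_len(epochs)) {
      noise <- matrix(rnorm(n * noise_dim), n)
      gin <- cbind(zs$Z, noise)
      gfwd <- mlp_fw(gp, gin, g_act)
      fake <- gfwd$out
      # --- discriminator step (fake detached) ---
      din_real <- cbind(Tm, zs$Z)
      din_fake <- cbind(fake, zs$Z)
      dr <- mlp_fw(dp, din_real, d_act)
      df <- mlp_fw(dp, din_fake, d_act)
      lr_real <- bce_logits(dr$out, 1)
      lr_fake <- bce_logits(df$out, 0)
      if (!is.finite(lr_real$loss) || !is.finite(lr_fake$loss)) {
        stop_ctrender("GAN training diverged (non-finite discriminator loss).",
                      class = "ctrender_divergence_error")
      }
      gr <- mlp_bw(dp, dr$cache, d_act, lr_real$ds)
      gf <- mlp_bw(dp, df$cache, d_act, lr_fake$ds)
      dgrads <- purrr::map2(gr, gf, `+`)
      upd <- adam_step(dp, dgrads, ds, lr)
      dp <- upd$params
      ds <- upd$state
      # --- generator step: fool D + reconstruct target ---
      df2 <- mlp_fw(dp, cbind(fake, zs$Z), d_act)
      adv <- bce_logits(df2$out, 1)
      if (!is.finite(adv$loss)) {
        stop_ctrender("GAN training diverged (non-finite generator loss).",
                      class = "ctrender_divergence_error")
      }
      dback <- mlp_bw(dp, df2$cache, d_act, adv$ds)
      dfake <- dback$dX[, seq_len(HW), drop = FALSE] +
        lambda_rec * 2 * (fake - Tm) / (n * HW)
      ggrads <- mlp_bw(gp, gfwd$cache, g_act, dfake)
      upd <- adam_step(gp, ggrads, gs, lr)
      gp <- upd$params
      gs <- upd$state
    }
  })
  new_renderer("gan", gp, H, W, seed,
               list(activations = g_act, K = K, noise_dim = noise_dim,
                    disc = list(params = dp, activations = d_act)))
}

# discriminator scores (logits) for images (rows) given conditioning z
gan_discriminate <- function(renderer, images_flat, Z) {
  stopifnot(renderer$kind == "gan")
  mlp_fw(renderer$disc$params, cbind(images_flat, Z),
         renderer$disc$activations)$out
}

nerv_arch <- function(K, H, W) {
  h4 <- H %/% 4L
  w4 <- W %/% 4L
  list(h4 = h4, w4 = w4, c0 = 16L, c1 = 8L,
       mlp_sizes = c(12 + K, 128, h4 * w4 * 16L),
       mlp_act = c("relu", "relu"))
}

nerv_fw <- function(params, arch, Zin, H, W, keep_cache = TRUE) {
  B <- nrow(Zin)
  m <- mlp_fw(params[c("W1", "b1", "W2", "b2")], Zin, arch$mlp_act)
  X0 <- array(t(m$out), c(arch$h4, arch$w4, arch$c0, B))
  u1 <- convT_fw(X0, params$T1, params$tb1, 2L * arch$h4, 2L * arch$w4, 4, 2, 1)
  a1 <- relu_fw(u1$out)
  u2 <- convT_fw(a1, params$T2, params$tb2, H, W, 4, 2, 1)
  out <- tanh(u2$out)
  res <- list(out = out)
  if (keep_cache) res$cache <- list(m = m, X0 = X0, u1 = u1, a1 = a1, u2 = u2)
  res
}

nerv_bw <- function(params, arch, cache, dOut, H, W) {
  dU2 <- tanh_bw(tanh(cache$u2$out), dOut)
  g2 <- convT_bw(cache$u2, params$T2, dU2)
  dA1 <- relu_bw(cache$u1$out, g2$dX)
  g1 <- convT_bw(cache$u1, params$T1, dA1)
  B <- dim(cache$X0)[4]
  dM <- t(matrix(g1$dX, ncol = B))                 # B x (h4*w4*c0)
  gm <- mlp_bw(params[c("W1", "b1", "W2", "b2")], cache$m$cache, arch$mlp_act, dM)
  c(gm, list(T1 = g1$dW, tb1 = g1$db, T2 = g2$dW, tb2 = g2$db))
}

#' Train the NeRV-style index-conditioned renderer
#'
#' The network input is the concatenation of a 6-band positional encoding of
#' the sample's normalized index t and its class-probability vector z; an
#' MLP produces an `(H/4) x (W/4)` feature stack which two stride-2
#' transposed-convolution blocks upsample to `H x W` (Tanh output). Trained
#' with MSE against the target encoding, which is t-free, so t-sensitivity
#' stays bounded.
#'
#' @inheritParams train_decoder_renderer
#' @return A `ctrender_renderer` of kind "nerv".
#' @export
train_nerv_renderer <- function(feature_table, H = 32, W = 32, seed = 42,
                                epochs = 200, lr = 1e-3) {
  Z <- feature_z(feature_table)
  if (nrow(Z) < 10) stop_ctrender("Need at least 10 training samples.")
  if (H %% 4 != 0 || W %% 4 != 0) {
    stop_ctrender("NeRV renderer needs H and W divisible by 4.")
  }
  check_degenerate(Z)
  zs <- build_z_set(Z, derive_seed(seed, "nerv_data"))
  Tm <- target_matrix(zs$Z, H, W)
  K <- ncol(Z)
  arch <- nerv_arch(K, H, W)
  params <- mlp_init(arch$mlp_sizes, derive_seed(seed, "nerv_init"))
  local_seed(derive_seed(seed, "nerv_convt"), {
    params$T1 <- he_init(16 * arch$c1, arch$c0, 16 * arch$c0)
    params$tb1 <- numeric(arch$c1)
    params$T2 <- he_init(16 * 1, arch$c1, 16 * arch$c1)
    params$tb2 <- numeric(1)
  })
  state <- adam_init(params)
  PE <- positional_encode(zs$t, 6)
  Zin <- cbind(PE, zs$Z)
  n <- nrow(Zin)
  for (ep in seq_len(epochs)) {
    fwd <- nerv_fw(params, arch, Zin, H, W)
    Tarr <- array(t(Tm), c(H, W, 1, n))
    dOut <- 2 * (fwd$out - Tarr) / (n * H * W)
    grads <- nerv_bw(params, arch, fwd$cache, dOut, H, W)
    upd <- adam_step(params, grads, state, lr)
    params <- upd$params
    state <- upd$state
  }
  new_renderer("nerv", params, H, W, seed, list(K = K, arch = arch))
}

#' Render class-probability vectors into candidate images
#'
#' Deterministic inference for any trained renderer: the decoder consumes z,
#' the GAN consumes z with zeroed noise (unless supplied), and the
#' NeRV-style renderer consumes (positional encoding of t, z).
#'
#' @param renderer A trained `ctrender_renderer`.
#' @param Z Matrix of probability vectors (rows) or a single vector.
#' @param t Normalized indices in `[0, 1]` (NeRV only; default 0.5).
#' @param noise Optional noise matrix for the GAN path (default zeros).
#' @return A list of `H x W` matrices in `[-1, 1]`, one per row of `Z`.
#' @export
render <- function(renderer, Z, t = NULL, noise = NULL) {
  stopifnot(inherits(renderer, "ctrender_renderer"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  apply(Z, 1, validate_z)
  n <- nrow(Z)
  H <- renderer$H
  W <- renderer$W
  flat <- switch(renderer$kind,
    decoder = mlp_fw(renderer$params, Z, renderer$activations)$out,
    gan = {
      if (is.null(noise)) noise <- matrix(0, n, renderer$noise_dim)
      mlp_fw(renderer$params, cbind(Z, noise), renderer$activations)$out
    },
    nerv = {
      if (is.null(t)) t <- rep(0.5, n)
      if (length(t) == 1) t <- rep(t, n)
      PE <- positional_encode(t, 6)
      if (is.null(dim(PE))) PE <- matrix(PE, nrow = 1)
      out <- nerv_fw(renderer$params, renderer$arch, cbind(PE, Z), H, W,
                     keep_cache = FALSE)$out
      t(matrix(out, ncol = n))
    },
    stop_ctrender("Unknown renderer kind."))
  lapply(seq_len(n), function(i) matrix(flat[i, ], H, W))
}

#' Mean squared error of a renderer against the target encoding
#'
#' Evaluates the renderer on a uniform z-grid (step `step` along the first
#' class probability, complementary second class) and compares with
#' [target_encoding()] computed directly.
#'
#' @param renderer A trained `ctrender_renderer`.
#' @param step Grid step along `z1`.
#' @param t NeRV index used for evaluation.
#' @return Mean squared pixel error over the grid.
#' @export
renderer_grid_mse <- function(renderer, step = 0.1, t = 0.5) {
  z1 <- seq(0, 1, by = step)
  Z <- cbind(z1, 1 - z1)
  imgs <- render(renderer, Z, t = t)
  mse <- vapply(seq_len(nrow(Z)), function(i) {
    mean((imgs[[i]] - target_encoding(Z[i, ], renderer$H, renderer$W))^2)
  }, numeric(1))
  mean(mse)
}

#' Render all three candidates for every sample
#'
#' Produces one candidate set per feature-table row (order preserved):
#' decoder, GAN and NeRV renders of the sample's probability vector. The
#' NeRV index t is the sample's normalized position in the table.
#'
#' @param feature_table Feature tibble with `F1..FK` columns.
#' @param renderers List of three trained renderers covering the kinds
#'   decoder, gan and nerv.
#' @return A tibble: `index` (0-based), `image_id`, `label` (if present),
#'   and list-columns `decoder`, `gan`, `nerv`.
#' @export
render_all <- function(feature_table, renderers) {
  kinds <- vapply(renderers, function(r) r$kind, character(1))
  if (!setequal(kinds, c("decoder", "gan", "nerv"))) {
    stop_ctrender("`renderers` must contain exactly the kinds decoder, gan, nerv.",
                  class = "ctrender_renderer_error")
  }
  names(renderers) <- kinds
  n <- nrow(feature_table)
  out <- tibble::tibble(index = seq_len(n) - 1L,
                        image_id = feature_table$image_id)
  if ("label" %in% names(feature_table)) out$label <- feature_table$label
  if (n == 0) {
    out$decoder <- list()
    out$gan <- list()
    out$nerv <- list()
    return(out)
  }
  Z <- feature_z(feature_table)
  tvec <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  out$decoder <- render(renderers$decoder, Z)
  out$gan <- render(renderers$gan, Z)
  out$nerv <- render(renderers$nerv, Z, t = tvec)
  out
}

# [-1,1] renders <-> 8-bit storage
render_to_uint8 <- function(m) {
  matrix(as.integer(round_half_up((m + 1) / 2 * 255)), nrow(m))
}

#' Write candidate images as PNG files
#'
#' Persists every candidate under `<out_dir>/<kind>/<class>/img_<index>.png`
#' with the linear 8-bit mapping -1 -> 0, +1 -> 255.
#'
#' @param candidates Tibble from [render_all()].
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_candidate_images <- function(candidates, out_dir) {
  paths <- character(0)
  for (kind in c("decoder", "gan", "nerv")) {
    for (i in seq_len(nrow(candidates))) {
      cls <- if ("label" %in% names(candidates)) candidates$label[i] else "all"
      dir <- file.path(out_dir, kind, cls)
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(dir, sprintf("img_%d.png", candidates$index[i]))
      png::writePNG(render_to_uint8(candidates[[kind]][[i]]) / 255, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @export
print.ctrender_renderer <- function(x, ...) {
  cat(sprintf("<ctrender_renderer: %s, %dx%d, seed=%d>\n", x$kind, x$H, x$W,
              x$seed))
  invisible(x)
}
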