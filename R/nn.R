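# Internal neural-network primitives.
#
# All trainable networks in the package (reference CNN backbone, decoder-MLP
# renderer, conditional GAN, NeRV-style renderer, small residual extractor)
# run on these primitives: batched im2col/col2im convolutions that reduce to
# BLAS matrix products, dense layers, and Adam. Gradients are verified by
# finite differences in the test suite. Layout convention: image batches are
# arrays dim (H, W, C, B); dense activations are matrices (B, n).

.plan_cache <- new.env(parent = emptyenv())

# Index plan for im2col over a batch: idx is a (B*oH*oW) x (k*k*C) matrix of
# linear indices into the padded batch array (Hp, Wp, C, B). Rows are blocked
# by image, within-image positions column-major (row index fastest); column
# blocks of size k*k per input channel, kernel offsets with ki fastest.
conv_plan <- function(H, W, C, B, k, s, p) {
  key <- paste(H, W, C, B, k, s, p, sep = "_")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  oH <- (Hp - k) %/% s + 1L
  oW <- (Wp - k) %/% s + 1L
  oi <- rep(seq_len(oH), times = oW)
  oj <- rep(seq_len(oW), each = oH)
  base_t <- ((oj - 1L) * s) * Hp + (oi - 1L) * s       # 0-based plane offset
  ki <- rep(seq_len(k), times = k)
  kj <- rep(seq_len(k), each = k)
  off_u <- (kj - 1L) * Hp + ki                          # 1-based within plane
  plane <- outer(base_t, off_u, `+`)                    # oHW x k*k
  oHW <- oH * oW
  kk <- k * k
  idx <- matrix(0, nrow = B * oHW, ncol = kk * C)
  plane_sz <- Hp * Wp
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * oHW + 1L):(b * oHW)
    for (cch in seq_len(C)) {
      cols <- ((cch - 1L) * kk + 1L):(cch * kk)
      idx[rows, cols] <- plane + ((b - 1L) * C + (cch - 1L)) * plane_sz
    }
  }
  plan <- list(idx = idx, H = H, W = W, C = C, B = B, k = k, s = s, p = p,
               Hp = Hp, Wp = Wp, oH = oH, oW = oW)
  .plan_cache[[key]] <- plan
  plan
}

pad_batch <- function(X, p) {
  if (p == 0L) return(X)
  d <- dim(X)
  Xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3], d[4]))
  Xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , ] <- X
  Xp
}

unpad_batch <- function(Xp, p, H, W) {
  if (p == 0L) return(Xp)
  Xp[(p + 1L):(p + H), (p + 1L):(p + W), , , drop = FALSE]
}

im2col <- function(Xp, plan) {
  matrix(Xp[plan$idx], nrow = nrow(plan$idx))
}

col2im <- function(dP, plan) {
  acc <- numeric(plan$Hp * plan$Wp * plan$C * plan$B)
  idx <- plan$idx
  for (u in seq_len(ncol(idx))) {
    iu <- idx[, u]
    acc[iu] <- acc[iu] + dP[, u]
  }
  array(acc, c(plan$Hp, plan$Wp, plan$C, plan$B))
}

# rows of a (B*oHW) x Cout matrix -> array (oH, oW, Cout, B)
rows_to_array <- function(Y, oH, oW, Cout, B) {
  out <- array(0, c(oH, oW, Cout, B))
  oHW <- oH * oW
  for (b in seq_len(B)) {
    out[, , , b] <- array(Y[((b - 1L) * oHW + 1L):(b * oHW), ], c(oH, oW, Cout))
  }
  out
}

array_to_rows <- function(A) {
  d <- dim(A)  # oH oW C B
  oHW <- d[1] * d[2]
  Y <- matrix(0, nrow = oHW * d[4], ncol = d[3])
  for (b in seq_len(d[4])) {
    Y[((b - 1L) * oHW + 1L):(b * oHW), ] <- matrix(A[, , , b], nrow = oHW)
  }
  Y
}

# Convolution forward. W: (k*k*Cin) x Cout, b: length Cout.
conv_fw <- function(X, Wm, bv, k, s, p) {
  d <- dim(X)
  plan <- conv_plan(d[1], d[2], d[3], d[4], k, s, p)
  P <- im2col(pad_batch(X, p), plan)
  Y <- P %*% Wm
  Y <- Y + rep(bv, each = nrow(Y))
  list(out = rows_to_array(Y, plan$oH, plan$oW, ncol(Wm), d[4]),
       P = P, plan = plan)
}

conv_bw <- function(cache, Wm, dOut) {
  plan <- cache$plan
  dY <- array_to_rows(dOut)
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, Wm)
  dXp <- col2im(dP, plan)
  dX <- unpad_batch(dXp, plan$p, plan$H, plan$W)
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution (stride-2 upsampling). Win is the weight matrix of
# the adjoint convolution large->small: (k*k*Clarge) x Csmall. Forward maps a
# small input (h, w, Csmall, B) onto the large grid via col2im; bias is per
# large channel.
convT_fw <- function(X, Win, bv, Hout, Wout, k, s, p) {
  d <- dim(X)
  Clarge <- nrow(Win) / (k * k)
  plan <- conv_plan(Hout, Wout, Clarge, d[4], k, s, p)
  stopifnot(plan$oH == d[1], plan$oW == d[2])
  Xm <- array_to_rows(X)
  dP <- tcrossprod(Xm, Win)           # (B*hw) x (k*k*Clarge)
  Yp <- col2im(dP, plan)
  Y <- unpad_batch(Yp, p, Hout, Wout)
  Y <- sweep(Y, 3, bv, "+")
  list(out = Y, Xm = Xm, plan = plan)
}

convT_bw <- function(cache, Win, dOut) {
  plan <- cache$plan
  dYp <- pad_batch(dOut, plan$p)
  Pd <- matrix(dYp[plan$idx], nrow = nrow(plan$idx))   # im2col of upstream grad
  dXm <- Pd %*% Win
  dW <- crossprod(Pd, cache$Xm)
  d <- dim(dOut)
  db <- colSums(matrix(aperm(dOut, c(1, 2, 4, 3)), ncol = d[3]))
  dX <- rows_to_array(dXm, plan$oH, plan$oW, ncol(Win), plan$B)
  list(dX = dX, dW = dW, db = db)
}

relu_fw <- function(x) {
  x * (x > 0)
}

relu_bw <- function(x, dy) {
  dy * (x > 0)
}

tanh_bw <- function(y, dy) {
  dy * (1 - y^2)
}

gap_fw <- function(X) {
  d <- dim(X)
  m <- colMeans(matrix(X, nrow = d[1] * d[2]))         # length C*B
  t(matrix(m, nrow = d[3]))                             # B x C
}

gap_bw <- function(dY, d) {
  # dY: B x C; replicate over spatial positions
  per <- t(dY) / (d[1] * d[2])                          # C x B
  array(rep(as.numeric(per), each = d[1] * d[2]), d)
}

dense_fw <- function(X, Wm, bv) {
  Y <- X %*% Wm
  Y + rep(bv, each = nrow(Y))
}

dense_bw <- function(X, Wm, dY) {
  list(dX = tcrossprod(dY, Wm), dW = crossprod(X, dY), db = colSums(dY))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# mean cross-entropy over the batch; returns loss and dlogits
softmax_ce <- function(logits, y_onehot) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -sum(y_onehot * log(pmax(P, 1e-12))) / n
  list(loss = loss, dlogits = (P - y_onehot) / n, probs = P)
}

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- generic MLP (dense stacks used by the renderers) ----------------------

mlp_init <- function(sizes, seed) {
  local_seed(seed, {
    params <- list()
    for (i in seq_len(length(sizes) - 1L)) {
      params[[paste0("W", i)]] <- he_init(sizes[i], sizes[i + 1L], sizes[i])
      params[[paste0("b", i)]] <- numeric(sizes[i + 1L])
    }
    params
  })
}

# activations: character vector per layer, from "relu", "tanh", "linear",
# "sigmoid"
mlp_fw <- function(params, X, activations) {
  nl <- length(activations)
  cache <- vector("list", nl)
  A <- X
  for (i in seq_len(nl)) {
    Z <- dense_fw(A, params[[paste0("W", i)]], params[[paste0("b", i)]])
    Ai <- switch(activations[i],
                 relu = relu_fw(Z),
                 tanh = tanh(Z),
                 sigmoid = 1 / (1 + exp(-Z)),
                 linear = Z)
    cache[[i]] <- list(input = A, Z = Z, out = Ai)
    A <- Ai
  }
  list(out = A, cache = cache)
}

mlp_bw <- function(params, cache, activations, dOut) {
  grads <- list()
  dA <- dOut
  for (i in rev(seq_along(activations))) {
    cc <- cache[[i]]
    dZ <- switch(activations[i],
                 relu = relu_bw(cc$Z, dA),
                 tanh = tanh_bw(cc$out, dA),
                 sigmoid = dA * cc$out * (1 - cc$out),
                 linear = dA)
    g <- dense_bw(cc$input, params[[paste0("W", i)]], dZ)
    grads[[paste0("W", i)]] <- g$dW
    grads[[paste0("b", i)]] <- g$db
    dA <- g$dX
  }
  grads$dX <- dA   # gradient wrt the network input (ignored by adam_step)
  grads
}
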