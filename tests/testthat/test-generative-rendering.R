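test_that("target encoding has the designed geometry", {
  H <- 32
  t1 <- target_encoding(c(1, 0), H, H)
  # global maximum at the first anchor (half-pixel center (8, 8))
  peak <- which(t1 == max(t1), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak), c(8, 8), tolerance = 1)
  # corner far from both anchors decays to -1
  expect_equal(t1[H, 1], -1, tolerance = 1e-3)
  # symmetric mixture is symmetric under 180-degree rotation
  t5 <- target_encoding(c(0.5, 0.5), H, H)
  rot <- t5[H:1, H:1]
  expect_equal(t5, rot, tolerance = 1e-12)
  expect_true(all(t5 >= -1 & t5 <= 1))
  # invalid z rejected
  expect_error(target_encoding(c(0.7, 0.7)), class = "ctrender_z_error")
})

test_that("decoder_layer evaluates a single layer exactly", {
  expect_equal(decoder_layer(c(1, -1), diag(2), c(0, 0), "relu"), c(1, 0))
  # zero weights: constant max(c, 0) under ReLU
  expect_equal(decoder_layer(c(5, 5), matrix(0, 2, 2), c(-3, 2), "relu"),
               c(0, 2))
  # tanh final layer bounds outputs
  out <- decoder_layer(rnorm(4), matrix(rnorm(12), 3, 4), rnorm(3), "tanh")
  expect_true(all(out > -1 & out < 1))
  expect_error(decoder_layer(c(1, 2, 3), diag(2), c(0, 0)),
               class = "ctrender_dim_error")
})

test_that("positional encoding matches its closed form", {
  expect_equal(positional_encode(0, 2), c(0, 1, 0, 1))
  expect_equal(positional_encode(0.5, 2), c(1, 0, 0, -1), tolerance = 1e-12)
  expect_length(positional_encode(0.3, 6), 12)
  expect_error(positional_encode(1.2), class = "ctrender_t_error")
})

test_that("decoder renderer memorizes a single z and trains deterministically", {
  ft1 <- tibble::tibble(image_id = sprintf("r%02d", 1:20),
                        F1 = rep(0.35, 20), F2 = rep(0.65, 20))
  expect_warning(dm <- train_decoder_renderer(ft1, seed = 1, epochs = 250),
                 "constant")
  tz <- target_encoding(c(0.35, 0.65), 32, 32)
  img <- render(dm, c(0.35, 0.65))[[1]]
  expect_lt(mean((img - tz)^2), 1e-3)
  expect_true(all(img >= -1 & img <= 1))
  # determinism: identical weights from identical seeds
  dm2 <- suppressWarnings(train_decoder_renderer(ft1, seed = 1, epochs = 250))
  expect_identical(dm$params, dm2$params)
  expect_error(train_decoder_renderer(ft1[1:5, ]), "at least 10")
})

test_that("GAN inference is deterministic at zero noise and its discriminator separates", {
  ft <- synthetic_feature_table(n = 60, seed = 2)
  gan <- train_gan_renderer(ft, seed = 8, epochs = 40)
  i1 <- render(gan, c(0.6, 0.4))[[1]]
  i2 <- render(gan, c(0.6, 0.4))[[1]]
  expect_identical(i1, i2)
  # early in training real targets and generator outputs are still disjoint
  # and the discriminator must already separate them
  gan5 <- train_gan_renderer(ft, seed = 8, epochs = 5)
  Z <- ctrender:::feature_z(ft[1:20, ])
  real <- ctrender:::target_matrix(Z, 32, 32)
  fake <- do.call(rbind, lapply(render(gan5, Z), as.numeric))
  s_real <- ctrender:::gan_discriminate(gan5, real, Z)
  s_fake <- ctrender:::gan_discriminate(gan5, fake, Z)
  acc <- mean(c(s_real > 0, s_fake <= 0))
  expect_gt(acc, 0.5)
})

test_that("NeRV renderer is index-conditioned but target-faithful", {
  ft <- synthetic_feature_table(n = 80, seed = 3)
  nrv <- train_nerv_renderer(ft, seed = 4, epochs = 120)
  # determinism at fixed (z, t)
  expect_identical(render(nrv, c(0.7, 0.3), t = 0.25),
                   render(nrv, c(0.7, 0.3), t = 0.25))
  # t-sensitivity exists but is bounded (the target is t-free)
  d <- mean(abs(render(nrv, c(0.7, 0.3), t = 0)[[1]] -
                  render(nrv, c(0.7, 0.3), t = 1)[[1]]))
  expect_lte(d, 0.1)
})

test_that("render_all conserves counts and validates renderer kinds", {
  ft <- synthetic_feature_table(n = 10, seed = 5)
  dec <- suppressWarnings(train_decoder_renderer(ft, seed = 1, epochs = 30))
  gan <- train_gan_renderer(ft, seed = 1, epochs = 15)
  nrv <- train_nerv_renderer(ft, seed = 1, epochs = 15)
  cand <- render_all(ft, list(dec, gan, nrv))
  expect_equal(nrow(cand), 10)
  n_candidates <- sum(vapply(c("decoder", "gan", "nerv"),
                             function(k) length(cand[[k]]), integer(1)))
  expect_equal(n_candidates, 30)   # 3 per sample
  expect_equal(cand$index, 0:9)
  # missing kind
  expect_error(render_all(ft, list(dec, gan)), class = "ctrender_renderer_error")
  # empty table
  empty <- render_all(ft[0, ], list(dec, gan, nrv))
  expect_equal(nrow(empty), 0)
})

test_that("8-bit persistence maps the pixel range linearly", {
  m <- matrix(c(-1, 0, 1, 0.5), 2)
  u <- ctrender:::render_to_uint8(m)
  expect_equal(as.vector(u), c(0L, 128L, 255L, 191L))
  td <- withr::local_tempdir()
  ft <- synthetic_feature_table(n = 10, seed = 5)
  dec <- suppressWarnings(train_decoder_renderer(ft, seed = 1, epochs = 10))
  gan <- train_gan_renderer(ft, seed = 1, epochs = 5)
  nrv <- train_nerv_renderer(ft, seed = 1, epochs = 5)
  cand <- render_all(ft, list(dec, gan, nrv))
  paths <- write_candidate_images(cand, td)
  expect_length(paths, 30)
  expect_true(all(file.exists(paths)))
  expect_match(paths[1], "decoder/(mesothelioma|non_mesothelioma)/img_0\\.png")
})

test_that("rendering preserves class signal for a linear probe", {
  ft <- synthetic_feature_table(n = 120, seed = 6)
  dec <- train_decoder_renderer(ft, H = 16, W = 16, seed = 2, epochs = 200)
  imgs <- render(dec, ctrender:::feature_z(ft))
  X_img <- t(vapply(imgs, as.numeric, numeric(256)))
  X_z <- ctrender:::feature_z(ft)
  set.seed(10)
  tr <- sample(c(TRUE, FALSE), 120, replace = TRUE, prob = c(0.7, 0.3))
  y <- ft$label
  probe <- function(X) {
    fit <- train_logreg(X[tr, ], y[tr])
    mean(predict(fit, X[!tr, ]) == y[!tr])
  }
  expect_gte(probe(X_img), probe(X_z) - 0.02)
})
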