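make_candidates <- function(mats_by_kind, labels) {
  n <- length(labels)
  tibble::tibble(index = seq_len(n) - 1L,
                 image_id = sprintf("c%03d", seq_len(n)),
                 label = labels,
                 decoder = mats_by_kind$decoder,
                 gan = mats_by_kind$gan,
                 nerv = mats_by_kind$nerv)
}

test_that("centroids are arithmetic means of pooled flattened candidates", {
  m <- function(v) matrix(v, 1, 2)
  cand <- make_candidates(
    list(decoder = list(m(c(0, 0)), m(c(4, 4))),
         gan = list(m(c(1, 1)), m(c(5, 5))),
         nerv = list(m(c(2, 2)), m(c(6, 6)))),
    c("mesothelioma", "non_mesothelioma"))
  cents <- fit_centroids(cand)
  expect_equal(cents$centroids$mesothelioma, c(1, 1))
  expect_equal(cents$centroids$non_mesothelioma, c(5, 5))
  # brute-force oracle on random candidates
  set.seed(11)
  mats <- replicate(5, matrix(rnorm(4), 2), simplify = FALSE)
  cand2 <- make_candidates(
    list(decoder = mats, gan = mats, nerv = mats),
    c("mesothelioma", "mesothelioma", "non_mesothelioma",
      "non_mesothelioma", "mesothelioma"))
  cents2 <- fit_centroids(cand2)
  meso <- mats[c(1, 2, 5)]
  brute <- colMeans(do.call(rbind, lapply(rep(meso, 3), as.numeric)))
  expect_equal(cents2$centroids$mesothelioma, brute)
  # missing class errors
  expect_error(fit_centroids(cand[1, ]), class = "ctrender_label_error")
})

test_that("discriminative score matches hand-computed Euclidean ratios", {
  expect_equal(discriminative_score(c(0, 0), c(1, 0), c(3, 0)), 3)
  # equidistant -> 1
  expect_equal(discriminative_score(c(0, 1), c(1, 1), c(-1, 1)), 1)
  # coincidence with own centroid -> capped sentinel
  expect_equal(discriminative_score(c(2, 2), c(2, 2), c(5, 6)),
               5 / 1e-12)
  expect_error(discriminative_score(c(1, 2, 3), c(0, 0), c(1, 1)),
               class = "ctrender_dim_error")
  # 100 random triples against the direct formula
  set.seed(12)
  for (i in 1:100) {
    m <- rnorm(8); cp <- rnorm(8); cn <- rnorm(8)
    expect_equal(discriminative_score(m, cp, cn),
                 sqrt(sum((m - cn)^2)) / sqrt(sum((m - cp)^2)),
                 tolerance = 1e-12)
  }
})

test_that("the score is invariant to joint rotation and global scaling", {
  set.seed(13)
  m <- rnorm(2); cp <- rnorm(2); cn <- rnorm(2)
  ds0 <- discriminative_score(m, cp, cn)
  for (th in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(discriminative_score(R %*% m, R %*% cp, R %*% cn), ds0,
                 tolerance = 1e-12)
  }
  for (a in c(0.01, 5, 1000)) {
    expect_equal(discriminative_score(a * m, a * cp, a * cn), ds0,
                 tolerance = 1e-9)
  }
})

test_that("representative selection maximizes the score with the fixed tie order", {
  # engineered: decoder sits near the own-class centroid, others at midpoint
  own <- c(1, 1, 1, 1)
  rival <- c(-1, -1, -1, -1)
  mid <- (own + rival) / 2
  cand <- make_candidates(
    list(decoder = list(matrix(own + 0.01, 2)),
         gan = list(matrix(mid, 2)),
         nerv = list(matrix(mid, 2))),
    "mesothelioma")
  cents <- structure(list(centroids = list(mesothelioma = own,
                                           non_mesothelioma = rival),
                          fit_ids = "c001"),
                     class = "class_centroids")
  sel <- select_representatives(cand, cents)
  expect_equal(sel$selected_method, "decoder")
  # brute force over the three DS values on random candidate sets
  set.seed(14)
  for (rep in 1:10) {
    mats <- replicate(3, matrix(rnorm(4), 2), simplify = FALSE)
    cand2 <- make_candidates(list(decoder = mats[1], gan = mats[2],
                                  nerv = mats[3]), "mesothelioma")
    sel2 <- select_representatives(cand2, cents)
    ds <- vapply(mats, function(mm) {
      discriminative_score(as.numeric(mm), own, rival)
    }, numeric(1))
    expect_equal(sel2$selected_method,
                 c("decoder", "gan", "nerv")[which.max(ds)])
  }
  # all-identical candidates -> decoder by the tie rule
  same <- matrix(rnorm(4), 2)
  cand3 <- make_candidates(list(decoder = list(same), gan = list(same),
                                nerv = list(same)), "mesothelioma")
  expect_equal(select_representatives(cand3, cents)$selected_method, "decoder")
  # orientation flag flips the choice
  sel_min <- select_representatives(cand, cents, orientation = "min_ratio")
  expect_false(sel_min$selected_method == "decoder")
})

test_that("one manifest row per sample, even at study scale", {
  set.seed(15)
  n <- 1008
  labels <- rep(c("Diseased", "No disease"), each = n / 2)
  mats <- lapply(seq_len(n), function(i) matrix(rnorm(4), 2))
  cand <- make_candidates(list(decoder = mats, gan = mats, nerv = mats),
                          labels)
  cents <- structure(list(centroids = list("Diseased" = c(1, 1, 1, 1),
                                           "No disease" = c(-1, -1, -1, -1)),
                          fit_ids = cand$image_id),
                     class = "class_centroids")
  sel <- select_representatives(cand, cents)
  expect_equal(nrow(sel), 1008)
  expect_equal(sel$index, 0:1007)
  expect_true(all(sel$selected_method %in% c("decoder", "gan", "nerv")))
})

test_that("variance selection agrees with a brute-force variance ranking", {
  # constant candidate never wins over textured ones
  flat <- matrix(0.5, 4, 4)
  tex <- matrix(rnorm(16), 4)
  cand <- make_candidates(list(decoder = list(flat), gan = list(tex),
                               nerv = list(flat)), "mesothelioma")
  expect_equal(variance_select(cand)$selected_method, "gan")
  # all-constant -> decoder by tie rule
  cand2 <- make_candidates(list(decoder = list(flat), gan = list(flat),
                                nerv = list(flat)), "mesothelioma")
  expect_equal(variance_select(cand2)$selected_method, "decoder")
  # ten random triplets against independent variance computation
  set.seed(16)
  for (rep in 1:10) {
    mats <- replicate(3, matrix(rnorm(16), 4), simplify = FALSE)
    cand3 <- make_candidates(list(decoder = mats[1], gan = mats[2],
                                  nerv = mats[3]), "x")
    vs <- vapply(mats, function(mm) var(as.numeric(mm)), numeric(1))
    expect_equal(variance_select(cand3)$selected_method,
                 c("decoder", "gan", "nerv")[which.max(vs)])
  }
})

test_that("manifest round-trips bit-exactly and validates on read", {
  sel <- tibble::tibble(index = 0:2,
                        selected_method = c("decoder", "gan", "nerv"),
                        label = c("Diseased", "Diseased", "No disease"),
                        image_path = c("decoder/Diseased/img_0.png",
                                       "gan/Diseased/img_1.png",
                                       "nerv/No disease/img_2.png"))
  td <- withr::local_tempdir()
  p <- file.path(td, "manifest.csv")
  write_manifest(sel, p)
  expect_identical(readLines(p)[1], "Index,Selected_Method,Label,Image_Path")
  back <- read_manifest(p)
  expect_identical(as.data.frame(back), as.data.frame(sel))
  # study-style row parses field by field
  writeLines(c("Index,Selected_Method,Label,Image_Path",
               "0,decoder,Diseased,decoder/Diseased/img_0.png"), p)
  one <- read_manifest(p)
  expect_equal(one$index, 0L)
  expect_equal(one$selected_method, "decoder")
  expect_equal(one$label, "Diseased")
  # header mismatch names the expected header
  writeLines(c("idx,method,label,path", "0,decoder,a,b"), p)
  expect_error(read_manifest(p), "Index,Selected_Method,Label,Image_Path")
  # malformed row reports its line number
  writeLines(c("Index,Selected_Method,Label,Image_Path", "0,decoder,a,b",
               "not-a-row"), p)
  expect_error(read_manifest(p), "line 3")
})

test_that("selection recovers the clean renderer on corrupted candidates", {
  cand <- recovery_candidates(n = 100, seed = 7)
  cents <- fit_centroids(cand)
  sel <- select_representatives(cand, cents)
  recovery <- mean(sel$selected_method == attr(cand, "clean_kind"))
  expect_gte(recovery, 0.9)
})
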