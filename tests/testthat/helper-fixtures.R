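# Shared fixtures, memoised so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small separable cohort for unit tests (64 px keeps conv training quick)
tiny_cohort <- function() {
  memo_fixture("tiny_cohort", {
    generate_cohort(cohort_config(n_patients_per_class = 8, class_effect = 6,
                                  image_size = 64, noise_sd = 8, seed = 101))
  })
}

tiny_overlaid <- function() {
  memo_fixture("tiny_overlaid", segment_overlay_cohort(tiny_cohort()))
}

tiny_backbone <- function() {
  memo_fixture("tiny_backbone", {
    split <- grouped_split(tiny_overlaid(), "holdout", seed = 3)
    list(model = train_backbone(tiny_overlaid(),
                                backbone_spec(epochs = 4, input_size = 64),
                                split$train_ids),
         split = split)
  })
}

# synthetic corner-clustered class-probability table (bypasses the backbone)
synthetic_feature_table <- function(n = 300, seed = 9, spread = 0.05) {
  local({
    set.seed(seed)
    z1 <- c(pmin(pmax(rnorm(n / 2, 0.92, spread), 0), 1),
            pmin(pmax(rnorm(n / 2, 0.08, spread), 0), 1))
    tibble::tibble(
      image_id = sprintf("s%04d", seq_len(n)),
      label = rep(c("mesothelioma", "non_mesothelioma"), each = n / 2),
      F1 = z1, F2 = 1 - z1)
  })
}

# candidate sets where one renderer carries the clean target encoding and
# the other two are corrupted towards the opposite class centroid
recovery_candidates <- function(n = 200, seed = 42, noise_sd = 0.3,
                                H = 16, W = 16) {
  set.seed(seed)
  labels <- rep(c("mesothelioma", "non_mesothelioma"), each = n / 2)
  z1 <- ifelse(labels == "mesothelioma", runif(n, 0.75, 0.98),
               runif(n, 0.02, 0.25))
  opp_target <- function(zi) target_encoding(c(1 - zi, zi), H, W)
  kinds <- c("decoder", "gan", "nerv")
  clean_kind <- sample(kinds, n, replace = TRUE)
  cand <- tibble::tibble(index = seq_len(n) - 1L,
                         image_id = sprintf("r%04d", seq_len(n)),
                         label = labels)
  mats <- list(decoder = vector("list", n), gan = vector("list", n),
               nerv = vector("list", n))
  for (i in seq_len(n)) {
    clean <- target_encoding(c(z1[i], 1 - z1[i]), H, W)
    for (k in kinds) {
      mats[[k]][[i]] <- if (k == clean_kind[i]) clean else {
        0.4 * clean + 0.6 * opp_target(z1[i]) +
          matrix(rnorm(H * W, sd = noise_sd), H, W)
      }
    }
  }
  cand$decoder <- mats$decoder
  cand$gan <- mats$gan
  cand$nerv <- mats$nerv
  attr(cand, "clean_kind") <- clean_kind
  cand
}

# moderate end-to-end ablation grid shared across pipeline-level tests
shared_grid <- function() {
  memo_fixture("shared_grid", {
    cfg <- pipeline_config(
      cohort = cohort_config(n_patients_per_class = 12, class_effect = 6,
                             image_size = 64, seed = 19),
      backbone = backbone_spec(epochs = 4, input_size = 64),
      renderer = list(H = 32, W = 32, decoder_epochs = 150, gan_epochs = 80,
                      nerv_epochs = 80),
      extractor = list(epochs = 3),
      boot_B = 0,
      seed = 23)
    run_ablation_grid(cfg)
  })
}

grid_acc <- function(grid, scenario_name, scheme_name) {
  grid$acc[grid$scenario == scenario_name & grid$scheme == scheme_name]
}

# minimal but complete pipeline configuration (for end-to-end contracts
# where accuracy is not the point)
tiny_pipeline_config <- function(seed = 51, ...) {
  pipeline_config(
    cohort = cohort_config(n_patients_per_class = 6, class_effect = 6,
                           image_size = 32, seed = 61),
    backbone = backbone_spec(epochs = 2, input_size = 32),
    renderer = list(H = 32, W = 32, decoder_epochs = 60, gan_epochs = 30,
                    nerv_epochs = 30),
    extractor = list(epochs = 2),
    boot_B = 0,
    seed = seed,
    ...)
}

tiny_run <- function() {
  memo_fixture("tiny_run", run_pipeline(tiny_pipeline_config()))
}
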