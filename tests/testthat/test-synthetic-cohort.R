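test_that("cohort generation is deterministic, balanced and count-conserving", {
  cfg <- cohort_config(n_patients_per_class = 5, image_size = 64, seed = 7)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$pixels, coh2$pixels)
  expect_identical(coh1$image_id, coh2$image_id)
  # patient/label integrity and balance
  pat <- dplyr::distinct(coh1, patient_id, label)
  expect_false(any(duplicated(pat$patient_id)))
  expect_equal(unname(table(pat$label)["mesothelioma"]), 5)
  expect_equal(unname(table(pat$label)["non_mesothelioma"]), 5)
  # count conservation: images = sum of per-patient slice counts
  per_pat <- table(coh1$patient_id)
  expect_equal(nrow(coh1), sum(per_pat))
  expect_true(all(per_pat >= 1 & per_pat <= 12))
  # pixel range and ids
  expect_true(all(vapply(coh1$pixels, function(p) all(p >= 0 & p <= 255),
                         logical(1))))
  expect_false(any(duplicated(coh1$image_id)))
})

test_that("slices_total pins the per-class image count to the study size", {
  cfg <- cohort_config(n_patients_per_class = 86, slices_total = 504,
                       image_size = 32, seed = 42)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 1008)
  expect_equal(length(unique(coh$patient_id)), 172)
  expect_equal(sum(coh$label == "mesothelioma"), 504)
})

test_that("zero class effect removes the rim difference", {
  cfg <- cohort_config(n_patients_per_class = 1, slices_mean = 1,
                       class_effect = 0, noise_sd = 0, image_size = 64,
                       seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 2)
  w <- vapply(coh$pixels, measure_rim_width, numeric(1))
  expect_equal(w[1], w[2], tolerance = 0.3)
})

test_that("class effect shows up monotonically in measured rim width", {
  coh <- generate_cohort(cohort_config(n_patients_per_class = 25,
                                       class_effect = 6, image_size = 64,
                                       seed = 13))
  w <- vapply(coh$pixels, measure_rim_width, numeric(1))
  mw <- tapply(w, coh$label, mean)
  expect_gt(mw["mesothelioma"], mw["non_mesothelioma"])
  # the gap must clear the noise-induced jitter decisively
  expect_gt(mw["mesothelioma"] - mw["non_mesothelioma"],
            2 * sd(w[coh$label == "non_mesothelioma"]))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_patients_per_class = 0), class = "ctrender_config_error")
  expect_error(cohort_config(slices_mean = -1), class = "ctrender_config_error")
  expect_error(cohort_config(image_size = 16), class = "ctrender_config_error")
  expect_error(cohort_config(class_effect = -2), class = "ctrender_config_error")
})

test_that("demographic sampling is seeded and tracks the study marginals", {
  d1 <- sample_demographics(172, seed = 5)
  d2 <- sample_demographics(172, seed = 5)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 172)
  expect_true(all(d1$age > 0))
  expect_true(all(d1$stage %in% 1:4))
  # binomial 99% band around the asbestos sampling probability 131/172
  p <- 131 / 172
  band <- qbinom(c(0.005, 0.995), 172, p)
  expect_gte(sum(d1$asbestos), band[1])
  expect_lte(sum(d1$asbestos), band[2])
  # n = 1: a single fully-populated record
  one <- sample_demographics(1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_false(any(is.na(unlist(one))))
})

test_that("summarize_cohort reproduces exact percentage arithmetic", {
  prof <- study_demographic_profile()
  yes <- function(f) prof$count[prof$field == f & prof$level == "yes"]
  records <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:172),
    asbestos = rep(c(TRUE, FALSE), c(yes("asbestos"), 172 - yes("asbestos"))),
    smoking = rep(c(TRUE, FALSE), c(yes("smoking"), 172 - yes("smoking"))),
    weight_loss = rep(c(TRUE, FALSE), c(yes("weight_loss"),
                                        172 - yes("weight_loss"))))
  s <- summarize_cohort(records)
  get <- function(f) s$pct[s$field == f & s$level == "yes"]
  expect_equal(get("asbestos"), 76.2)
  expect_equal(get("smoking"), 56.4)
  expect_equal(get("weight_loss"), 66.9)
  # zero-positive case reports 0.0
  z <- summarize_cohort(tibble::tibble(patient_id = "a", smoking = FALSE))
  expect_equal(z$pct[z$level == "no"], 100)
  expect_false("yes" %in% z$level[z$field == "smoking"] &&
                 z$pct[z$field == "smoking" & z$level == "yes"] != 0)
  expect_error(summarize_cohort(tibble::tibble()), class = "ctrender_error")
})
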