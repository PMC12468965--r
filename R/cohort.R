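#' Configuration for the synthetic CT-phantom cohort
#'
#' The generator emulates the structure of a two-class chest-CT study cohort:
#' balanced patients per class, several slices per patient, and a
#' class-dependent morphological signal. Mesothelioma presents on CT as
#' pleural thickening, so the phantom encodes the positive class as a
#' thickened pleural rim around the lung fields plus a few nodular bumps.
#'
#' @param n_patients_per_class Number of patients in each class (>= 1).
#' @param slices_mean Expected CT slices per patient; counts are drawn from a
#'   Poisson with this mean, clipped to `[1, 12]`.
#' @param slices_total Optional exact total slices per class. When given, the
#'   Poisson draws are adjusted (still within `[1, 12]` per patient) until the
#'   per-class total matches, which reproduces fixed-size study designs.
#' @param image_size Pixels per side of the square slice (>= 32).
#' @param class_effect Additional pleural-rim thickness, in pixels, for the
#'   mesothelioma class (>= 0). Zero removes the class signal.
#' @param rim_base Baseline rim thickness in pixels shared by both classes.
#' @param noise_sd Standard deviation of additive Gaussian noise, in 8-bit
#'   intensity units.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients_per_class = 86,
                          slices_mean = 5.8,
                          slices_total = NULL,
                          image_size = 128,
                          class_effect = 4,
                          rim_base = 3,
                          noise_sd = 8,
                          seed = 42) {
  if (!is_count(n_patients_per_class)) {
    stop_ctrender("`n_patients_per_class` must be a positive integer.",
                  class = "ctrender_config_error")
  }
  if (!is.numeric(slices_mean) || slices_mean <= 0) {
    stop_ctrender("`slices_mean` must be > 0.", class = "ctrender_config_error")
  }
  if (!is_count(image_size) || image_size < 32) {
    stop_ctrender("`image_size` must be an integer >= 32.",
                  class = "ctrender_config_error")
  }
  if (!is.numeric(class_effect) || class_effect < 0) {
    stop_ctrender("`class_effect` must be >= 0.", class = "ctrender_config_error")
  }
  if (!is.null(slices_total) && !is_count(slices_total)) {
    stop_ctrender("`slices_total` must be NULL or a positive integer.",
                  class = "ctrender_config_error")
  }
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 slices_mean = slices_mean,
                 slices_total = slices_total,
                 image_size = as.integer(image_size),
                 class_effect = class_effect,
                 rim_base = rim_base,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

cohort_classes <- function() c("mesothelioma", "non_mesothelioma")

# Poisson slice counts clipped to [1, 12]; optionally adjusted to an exact
# per-class total by nudging random patients up or down one slice at a time.
draw_slice_counts <- function(n, mean, total = NULL) {
  counts <- pmin(pmax(rpois(n, mean), 1L), 12L)
  if (!is.null(total)) {
    if (total < n || total > 12L * n) {
      stop_ctrender("`slices_total` unreachable with [1,12] slices per patient.",
                    class = "ctrender_config_error")
    }
    while (sum(counts) != total) {
      if (sum(counts) < total) {
        i <- sample(which(counts < 12L), 1L)
        counts[i] <- counts[i] + 1L
      } else {
        i <- sample(which(counts > 1L), 1L)
        counts[i] <- counts[i] - 1L
      }
    }
  }
  counts
}

# One phantom slice: bright body ellipse, dark lung fields, bright pleural
# rim of the requested thickness, optional nodular bumps on the rim.
phantom_slice <- function(S, rim_left, rim_right, nodules, noise_sd,
                          lung_shift = c(0, 0)) {
  xs <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)   # row coordinate
  ys <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)    # column coordinate
  cx <- S / 2
  cy <- S / 2
  img <- matrix(0, S, S)
  body <- ((xs - cx) / (0.36 * S))^2 + ((ys - cy) / (0.44 * S))^2 <= 1
  img[body] <- 140
  lungs <- list(c(cx, cy - 0.20 * S), c(cx, cy + 0.20 * S))
  rims <- c(rim_left, rim_right)
  a <- 0.20 * S
  b <- 0.13 * S
  for (i in 1:2) {
    lc <- lungs[[i]] + lung_shift
    w <- rims[i]
    outer_e <- ((xs - lc[1]) / (a + w))^2 + ((ys - lc[2]) / (b + w))^2 <= 1
    inner_e <- ((xs - lc[1]) / a)^2 + ((ys - lc[2]) / b)^2 <= 1
    img[outer_e & !inner_e] <- 230
    img[inner_e] <- 30
  }
  if (!is.null(nodules) && nrow(nodules) > 0) {
    for (j in seq_len(nrow(nodules))) {
      side <- if (nodules$side[j] == 1L) lungs[[1]] else lungs[[2]]
      lc <- side + lung_shift
      th <- nodules$angle[j]
      px <- lc[1] + a * cos(th)
      py <- lc[2] + b * sin(th)
      nod <- (xs - px)^2 + (ys - py)^2 <= nodules$radius[j]^2
      img[nod & body] <- 230
    }
  }
  img <- img + matrix(rnorm(S * S, sd = noise_sd), S, S)
  matrix(as.integer(round_half_up(pmin(pmax(img, 0), 255))), S, S)
}

#' Generate a synthetic two-class CT-phantom cohort
#'
#' Produces a patient-structured cohort of grayscale thorax phantoms. Every
#' patient contributes a clipped-Poisson number of slices and carries exactly
#' one class label; mesothelioma patients get a pleural rim thickened by
#' `class_effect` pixels (with per-patient jitter) plus 1-3 nodular bumps.
#' The result is fully deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `image_id`, `patient_id`, `label` and a
#'   `pixels` list-column of integer matrices in `[0, 255]`. Patient-level
#'   demographics (see [sample_demographics()]) are attached as attribute
#'   `"demographics"` and retrievable with [cohort_demographics()].
#' @seealso [summarize_cohort()], [measure_rim_width()]
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  S <- config$image_size
  classes <- cohort_classes()
  local_seed(config$seed, {
    rows <- list()
    pid_counter <- 0L
    for (cl in classes) {
      n_pat <- config$n_patients_per_class
      counts <- draw_slice_counts(n_pat, config$slices_mean, config$slices_total)
      for (i in seq_len(n_pat)) {
        pid_counter <- pid_counter + 1L
        pid <- sprintf("P%03d", pid_counter)
        effect <- if (cl == "mesothelioma") config$class_effect else 0
        w_pat <- max(0.5, config$rim_base + effect + rnorm(1, sd = 0.5))
        nods <- NULL
        if (cl == "mesothelioma" && config$class_effect > 0) {
          n_nod <- sample(1:3, 1L)
          nods <- data.frame(side = sample(1:2, n_nod, replace = TRUE),
                             angle = runif(n_nod, 0, 2 * pi),
                             radius = runif(n_nod, 2, 4) + config$class_effect / 2)
        }
        for (sl in seq_len(counts[i])) {
          w_sl <- max(0.5, w_pat + rnorm(1, sd = 0.3))
          shift <- rnorm(2, sd = S / 100)
          px <- phantom_slice(S, w_sl, max(0.5, w_sl + rnorm(1, sd = 0.3)),
                              nods, config$noise_sd, shift)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            image_id = sprintf("%s_s%02d", pid, sl),
            patient_id = pid,
            label = cl,
            pixels = list(px))
        }
      }
    }
    images <- dplyr::bind_rows(rows)
    demo <- sample_demographics(2L * config$n_patients_per_class,
                                seed = derive_seed(config$seed, "demographics"))
    demo$patient_id <- unique(images$patient_id)
    attr(images, "demographics") <- demo
    attr(images, "cohort_config") <- config
    images
  })
}

#' Patient demographics attached to a generated cohort
#'
#' @param images A cohort tibble from [generate_cohort()].
#' @return The demographics tibble.
#' @export
cohort_demographics <- function(images) {
  demo <- attr(images, "demographics")
  if (is.null(demo)) {
    stop_ctrender("No demographics attached; was this tibble produced by generate_cohort()?")
  }
  demo
}

#' Marginal demographic profile of the study cohort
#'
#' Category counts (out of 172 patients) used both as sampling weights by
#' [sample_demographics()] and as the reference arithmetic for
#' [summarize_cohort()]: 98/74 male/female, stage 15/42/68/47, histology
#' 133/16/15/8 (epithelioid/biphasic/sarcomatoid/not determined), asbestos
#' exposure 131, smoking 97, pain 102, weight loss 115.
#'
#' @return A tibble with columns `field`, `level`, `count`.
#' @export
study_demographic_profile <- function() {
  tibble::tribble(
    ~field, ~level, ~count,
    "sex", "male", 98L,
    "sex", "female", 74L,
    "stage", "1", 15L,
    "stage", "2", 42L,
    "stage", "3", 68L,
    "stage", "4", 47L,
    "histology", "epithelioid", 133L,
    "histology", "biphasic", 16L,
    "histology", "sarcomatoid", 15L,
    "histology", "not_determined", 8L,
    "asbestos", "yes", 131L,
    "asbestos", "no", 41L,
    "smoking", "yes", 97L,
    "smoking", "no", 75L,
    "pain", "yes", 102L,
    "pain", "no", 70L,
    "weight_loss", "yes", 115L,
    "weight_loss", "no", 57L)
}

#' Sample synthetic patient demographics
#'
#' Fields are drawn independently with the marginal frequencies of
#' [study_demographic_profile()]; age is normal with mean 56.8 and SD 14.6
#' years, truncated to `[18, 95]`.
#'
#' @param n_patients Number of records (>= 1).
#' @param seed Integer seed.
#' @return A tibble with one row per patient: `patient_id`, `sex`, `age`,
#'   `stage`, `histology`, and logicals `asbestos`, `smoking`, `pain`,
#'   `weight_loss`.
#' @export
sample_demographics <- function(n_patients, seed = 42) {
  if (!is_count(n_patients)) {
    stop_ctrender("`n_patients` must be a positive integer.",
                  class = "ctrender_config_error")
  }
  prof <- study_demographic_profile()
  draw_level <- function(field) {
    sub <- prof[prof$field == field, ]
    sample(sub$level, n_patients, replace = TRUE, prob = sub$count)
  }
  local_seed(seed, {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n_patients)),
      sex = draw_level("sex"),
      age = round(pmin(pmax(rnorm(n_patients, 56.8, 14.6), 18), 95), 1),
      stage = as.integer(draw_level("stage")),
      histology = draw_level("histology"),
      asbestos = draw_level("asbestos") == "yes",
      smoking = draw_level("smoking") == "yes",
      pain = draw_level("pain") == "yes",
      weight_loss = draw_level("weight_loss") == "yes")
  })
}

#' Summarize cohort demographics
#'
#' Counts and percentages of total patients for every binary or categorical
#' demographic field, with percentages rounded half-up to one decimal (so 131
#' of 172 asbestos-exposed patients reports as 76.2).
#'
#' @param records A demographics tibble (as from [sample_demographics()] or
#'   [cohort_demographics()]).
#' @return A tibble with columns `field`, `level`, `n`, `pct`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_ctrender("`records` must be a non-empty data frame of demographics.")
  }
  n_total <- nrow(records)
  fields <- intersect(c("sex", "stage", "histology", "asbestos", "smoking",
                        "pain", "weight_loss"), names(records))
  out <- purrr::map_dfr(fields, function(f) {
    v <- records[[f]]
    if (is.logical(v)) v <- ifelse(v, "yes", "no")
    tab <- table(factor(v))
    tibble::tibble(field = f,
                   level = names(tab),
                   n = as.integer(tab),
                   pct = round_half_up(as.integer(tab) / n_total * 1000) / 10)
  })
  out
}

#' Measure the pleural-rim width of a phantom slice
#'
#' Quality-control measurement for the synthetic cohort: bright rim pixels
#' (above the midpoint of the phantom's body and rim intensities) are counted
#' and divided by the lung-field boundary length, giving an average rim
#' thickness in pixels. Used to verify that the generator's class effect is
#' actually present in pixel space.
#'
#' @param pixels Integer matrix in `[0, 255]`.
#' @return Estimated rim width in pixels (0 when no lung field is found).
#' @export
measure_rim_width <- function(pixels) {
  stopifnot(is.matrix(pixels))
  rim <- pixels > (140 + 230) / 2
  body <- pixels > (30 + 140) / 2
  filled <- EBImage::fillHull(EBImage::Image(body * 1))
  holes <- (as.matrix(filled) > 0) & !body
  if (sum(holes) == 0) return(0)
  # boundary length: hole pixels with at least one 4-neighbour outside
  S <- nrow(pixels)
  pad <- matrix(FALSE, S + 2, S + 2)
  pad[2:(S + 1), 2:(S + 1)] <- holes
  inner <- pad[2:(S + 1), 2:(S + 1)]
  nb <- pad[1:S, 2:(S + 1)] & pad[3:(S + 2), 2:(S + 1)] &
    pad[2:(S + 1), 1:S] & pad[2:(S + 1), 3:(S + 2)]
  boundary <- sum(inner & !nb)
  if (boundary == 0) return(0)
  sum(rim) / boundary
}
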