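#' Fit class centroids of rendered candidates
#'
#' For each class, the centroid is the arithmetic mean of all flattened
#' candidate images (all three renderers pooled) belonging to that class
#' within `fit_ids`. Centroids should be fitted on training-split samples
#' only and then applied to all samples, so selection never peeks at test
#' labels through the centroid estimates.
#'
#' @param candidates Tibble from [render_all()] (needs `label`).
#' @param fit_ids Image ids used for fitting (defaults to all).
#' @return A `class_centroids` object: named list of mean vectors plus the
#'   id set used.
#' @export
fit_centroids <- function(candidates, fit_ids = NULL) {
  stopifnot(is.data.frame(candidates), "label" %in% names(candidates))
  if (is.null(fit_ids)) fit_ids <- candidates$image_id
  sub <- candidates[candidates$image_id %in% fit_ids, ]
  classes <- unique(sub$label)
  if (length(classes) < 2) {
    stop_ctrender("Both classes must be represented in `fit_ids`.",
                  class = "ctrender_label_error")
  }
  cents <- lapply(classes, function(cl) {
    rows <- sub[sub$label == cl, ]
    vecs <- c(lapply(rows$decoder, as.numeric),
              lapply(rows$gan, as.numeric),
              lapply(rows$nerv, as.numeric))
    Reduce(`+`, vecs) / length(vecs)
  })
  names(cents) <- classes
  structure(list(centroids = cents, fit_ids = fit_ids),
            class = "class_centroids")
}

#' Discriminative score of a candidate vector
#'
#' `DS = d(m, C_neg) / d(m, C_pos)` with Euclidean distances: the ratio of
#' the distance to the rival-class centroid over the distance to the
#' own-class centroid. Larger values mean the candidate sits closer to its
#' own class and farther from the rival. When the candidate coincides with
#' its own centroid (distance below 1e-12) the score is the capped sentinel
#' `d(m, C_neg) / 1e-12`.
#'
#' @param m Flattened candidate image (numeric vector).
#' @param c_pos Own-class centroid.
#' @param c_neg Rival-class centroid.
#' @return The discriminative score (scalar).
#' @export
discriminative_score <- function(m, c_pos, c_neg) {
  m <- as.numeric(m)
  if (length(m) != length(c_pos) || length(m) != length(c_neg)) {
    stop_ctrender("`m` and the centroids must have equal dimensionality.",
                  class = "ctrender_dim_error")
  }
  d_pos <- sqrt(sum((m - c_pos)^2))
  d_neg <- sqrt(sum((m - c_neg)^2))
  if (d_pos < 1e-12) return(d_neg / 1e-12)
  d_neg / d_pos
}

candidate_kinds <- function() c("decoder", "gan", "nerv")

#' Select the best representative candidate per sample
#'
#' Scores each sample's three candidates with [discriminative_score()]
#' (own-label centroid as positive) and keeps the argmax; ties break in the
#' fixed order decoder, gan, nerv. The printed formula is maximized by good
#' representatives; `orientation = "min_ratio"` is exposed for the opposite
#' reading of the score.
#'
#' @param candidates Tibble from [render_all()] (needs `label` and the three
#'   candidate list-columns).
#' @param centroids A [fit_centroids()] result.
#' @param orientation `"max_ratio"` (default) or `"min_ratio"`.
#' @param path_root Prefix used when composing manifest image paths.
#' @return A selection manifest tibble: `index`, `selected_method`, `label`,
#'   `image_path`, plus working columns `image_id` and `pixels` (the
#'   selected candidate).
#' @export
select_representatives <- function(candidates, centroids,
                                   orientation = c("max_ratio", "min_ratio"),
                                   path_root = "") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(centroids, "class_centroids"))
  kinds <- candidate_kinds()
  if (!all(kinds %in% names(candidates))) {
    stop_ctrender("Missing candidate columns (need decoder, gan, nerv).",
                  class = "ctrender_candidate_error")
  }
  classes <- names(centroids$centroids)
  scores <- matrix(0, nrow(candidates), 3,
                   dimnames = list(NULL, kinds))
  for (i in seq_len(nrow(candidates))) {
    own <- as.character(candidates$label[i])
    rival <- setdiff(classes, own)[1]
    if (!own %in% classes) {
      stop_ctrender(sprintf("No centroid for class '%s'.", own),
                    class = "ctrender_label_error")
    }
    for (k in kinds) {
      cand <- candidates[[k]][[i]]
      if (is.null(cand)) {
        stop_ctrender(sprintf("Missing %s candidate for sample %d.", k, i),
                      class = "ctrender_candidate_error")
      }
      scores[i, k] <- discriminative_score(as.numeric(cand),
                                           centroids$centroids[[own]],
                                           centroids$centroids[[rival]])
    }
  }
  pick <- if (orientation == "max_ratio") {
    apply(scores, 1, which.max)
  } else {
    apply(scores, 1, which.min)
  }
  build_manifest(candidates, kinds[pick], path_root)
}

#' Variance-threshold candidate selection
#'
#' Label-blind alternative selector: per sample, keep the candidate with
#' the highest pixel variance (same decoder/gan/nerv tie order).
#'
#' @inheritParams select_representatives
#' @return A selection manifest tibble (same shape as
#'   [select_representatives()]).
#' @export
variance_select <- function(candidates, path_root = "") {
  kinds <- candidate_kinds()
  if (!all(kinds %in% names(candidates))) {
    stop_ctrender("Missing candidate columns (need decoder, gan, nerv).",
                  class = "ctrender_candidate_error")
  }
  vars <- vapply(kinds, function(k) {
    vapply(candidates[[k]], function(m) {
      if (is.null(m)) stop_ctrender("Missing candidate image.",
                                    class = "ctrender_candidate_error")
      v <- var(as.numeric(m))
      if (is.na(v)) 0 else v
    }, numeric(1))
  }, numeric(nrow(candidates)))
  if (is.null(dim(vars))) vars <- matrix(vars, nrow = 1)
  pick <- apply(vars, 1, which.max)
  build_manifest(candidates, kinds[pick], path_root)
}

build_manifest <- function(candidates, selected, path_root) {
  n <- nrow(candidates)
  label <- if ("label" %in% names(candidates)) as.character(candidates$label)
           else rep(NA_character_, n)
  tibble::tibble(
    index = candidates$index %||% (seq_len(n) - 1L),
    selected_method = selected,
    label = label,
    image_path = file.path(path_root, selected, label,
                           sprintf("img_%d.png", candidates$index %||% (seq_len(n) - 1L))),
    image_id = candidates$image_id,
    pixels = purrr::map2(seq_len(n), selected,
                         function(i, k) candidates[[k]][[i]]))
}

manifest_header <- function() "Index,Selected_Method,Label,Image_Path"

#' Write / read a selection manifest
#'
#' The on-disk format is a CSV with exactly the header
#' `Index,Selected_Method,Label,Image_Path` and one row per sample;
#' `read_manifest()` validates the header and the method column and reports
#' parse failures with their line number. Writing then reading is an
#' identity on the four canonical columns.
#'
#' @param manifest Selection manifest tibble.
#' @param path File path.
#' @return `write_manifest()` the path, invisibly; `read_manifest()` the
#'   manifest tibble.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("index", "selected_method", "label", "image_path") %in%
                  names(manifest)))
  lines <- c(manifest_header(),
             sprintf("%d,%s,%s,%s", manifest$index, manifest$selected_method,
                     manifest$label, manifest$image_path))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0 || lines[1] != manifest_header()) {
    stop_ctrender(sprintf("Malformed manifest: expected header '%s'.",
                          manifest_header()),
                  class = "ctrender_parse_error")
  }
  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    parts <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(parts) != 4 || is.na(suppressWarnings(as.integer(parts[1])))) {
      stop_ctrender(sprintf("Manifest parse error at line %d: '%s'", i + 1L,
                            body[i]),
                    class = "ctrender_parse_error")
    }
    if (!parts[2] %in% candidate_kinds()) {
      stop_ctrender(sprintf(
        "Manifest parse error at line %d: unknown method '%s'", i + 1L,
        parts[2]), class = "ctrender_parse_error")
    }
    tibble::tibble(index = as.integer(parts[1]), selected_method = parts[2],
                   label = parts[3], image_path = parts[4])
  })
  dplyr::bind_rows(rows)
}

#' Copy selected representative images into a class-wise tree
#'
#' Writes each sample's selected candidate under
#' `<out_dir>/selected/<class>/img_<index>.png`.
#'
#' @param manifest Selection manifest with the `pixels` working column.
#' @param out_dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_selected_images <- function(manifest, out_dir) {
  stopifnot("pixels" %in% names(manifest))
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    dir <- file.path(out_dir, "selected", manifest$label[i])
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(dir, sprintf("img_%d.png", manifest$index[i]))
    png::writePNG(render_to_uint8(manifest$pixels[[i]]) / 255, paths[i])
  }
  invisible(paths)
}
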