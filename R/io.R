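#' Write / read a cohort on disk
#'
#' Slices are stored as 8-bit grayscale PNGs under `<dir>/images/`, the
#' cohort table as `cohort.csv` with header `image_id,patient_id,label`, and
#' patient demographics as `demographics.csv`.
#'
#' @param images Cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   cohort tibble with the `pixels` list-column restored.
#' @export
write_cohort <- function(images, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(images))) {
    png::writePNG(images$pixels[[i]] / 255,
                  file.path(dir, "images", paste0(images$image_id[i], ".png")))
  }
  utils::write.csv(images[, c("image_id", "patient_id", "label")],
                   file.path(dir, "cohort.csv"), row.names = FALSE,
                   quote = FALSE)
  demo <- attr(images, "demographics")
  if (!is.null(demo)) {
    utils::write.csv(demo, file.path(dir, "demographics.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tab_path <- file.path(dir, "cohort.csv")
  if (!file.exists(tab_path)) {
    stop_ctrender(sprintf("No cohort.csv under '%s'.", dir),
                  class = "ctrender_parse_error")
  }
  tab <- tibble::as_tibble(utils::read.csv(tab_path,
                                           stringsAsFactors = FALSE))
  if (!all(c("image_id", "patient_id", "label") %in% names(tab))) {
    stop_ctrender("cohort.csv must have columns image_id,patient_id,label.",
                  class = "ctrender_parse_error")
  }
  tab$pixels <- lapply(tab$image_id, function(id) {
    px <- png::readPNG(file.path(dir, "images", paste0(id, ".png")))
    if (length(dim(px)) == 3) px <- px[, , 1]
    matrix(as.integer(round_half_up(px * 255)), nrow(px))
  })
  demo_path <- file.path(dir, "demographics.csv")
  if (file.exists(demo_path)) {
    attr(tab, "demographics") <-
      tibble::as_tibble(utils::read.csv(demo_path, stringsAsFactors = FALSE))
  }
  tab
}

report_to_list <- function(rep) {
  mac <- rep$metrics[rep$metrics$class == "macro", ]
  out <- list(n = rep$n, acc = mac$acc, se = mac$se, sp = mac$sp,
              pre = mac$pre, f_scr = mac$f_scr)
  if (!is.null(rep$auc)) out$auc <- rep$auc
  if (!is.null(rep$ci)) {
    out$ci <- lapply(rep$ci, function(ci) {
      list(estimate = ci$estimate, lower = ci$lower, upper = ci$upper)
    })
  }
  if (!is.null(rep$fold_confusions)) {
    out$fold_confusions <- lapply(rep$fold_confusions, function(cm) {
      list(tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn)
    })
  }
  out
}

# Persist the run's tabular artifacts, reports and a run manifest with
# seeds and file hashes; PNGs only on request.
persist_run <- function(run, out_dir) {
  dir.create(file.path(out_dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "features"), showWarnings = FALSE)
  write_cohort(run$images[, c("image_id", "patient_id", "label", "pixels")],
               file.path(out_dir, "cohort"))
  feat <- run$features
  utils::write.csv(feat[, setdiff(names(feat), "pixels")],
                   file.path(out_dir, "features", "features.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(run$manifest)) {
    dir.create(file.path(out_dir, "selected"), showWarnings = FALSE)
    write_manifest(run$manifest, file.path(out_dir, "selected",
                                           "manifest.csv"))
    if (run$config$write_images) {
      write_selected_images(run$manifest, out_dir)
      write_candidate_images(run$candidates, file.path(out_dir, "rendered"))
    }
  }
  for (nm in names(run$reports)) {
    jsonlite::write_json(report_to_list(run$reports[[nm]]),
                         file.path(out_dir, "reports", paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_manifest.json$", files)]
  hashes <- tools::md5sum(files[!grepl("[.]png$", files)])
  manifest <- list(
    seed = run$config$seed,
    selection = run$config$selection,
    classifier = run$config$classifier,
    stage_seconds = run$timings,
    artifact_md5 = as.list(setNames(unname(hashes),
                                    substring(names(hashes),
                                              nchar(out_dir) + 2))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
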