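#' Construct a mask set
#'
#' A mask set is the unit returned by any mask provider: a list of binary
#' masks matching the source image dimensions, optionally with per-mask
#' confidence scores.
#'
#' @param masks List of 0/1 integer matrices, all the same dimension.
#' @param scores Optional numeric vector of per-mask confidences in `[0, 1]`.
#' @return A `mask_set` object.
#' @export
mask_set <- function(masks = list(), scores = NULL) {
  stopifnot(is.list(masks))
  if (length(masks) > 0) {
    d1 <- dim(masks[[1]])
    for (m in masks) {
      if (!is.matrix(m) || !identical(dim(m), d1)) {
        stop_ctrender("All masks must be matrices of identical dimensions.",
                      class = "ctrender_dim_error")
      }
      if (!all(m %in% c(0, 1))) {
        stop_ctrender("Masks must be binary (0/1).")
      }
    }
  }
  if (!is.null(scores)) {
    stopifnot(length(scores) == length(masks), all(scores >= 0 & scores <= 1))
  }
  structure(list(masks = masks, scores = scores), class = "mask_set")
}

#' @export
length.mask_set <- function(x) length(x$masks)

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
label8 <- function(fg) {
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(fg * 1)))
  nl <- max(lab)
  if (nl <= 1) return(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-1, -W]), as.vector(lab[-H, -1])))   # up-right
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    roots <- vapply(seq_len(nl), find, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  lab
}

#' Threshold-based toy segmenter
#'
#' Desk-scale mask provider: Otsu threshold, 8-connected components, and an
#' area filter. Components are returned largest first. A blank (constant)
#' image yields an empty mask set rather than an error.
#'
#' @param pixels Grayscale matrix (any numeric range; thresholding is
#'   performed on the `[0, 1]`-normalized image).
#' @param min_area Minimum component area in pixels.
#' @return A [mask_set()].
#' @export
toy_segment <- function(pixels, min_area = 50) {
  stopifnot(is.matrix(pixels))
  rng <- range(pixels)
  if (diff(rng) == 0) return(mask_set())
  norm <- (pixels - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  fg <- norm > th
  if (!any(fg)) return(mask_set())
  lab <- label8(fg)
  areas <- table(lab[lab > 0])
  keep <- as.integer(names(areas)[areas >= min_area])
  if (length(keep) == 0) return(mask_set())
  keep <- keep[order(-areas[as.character(keep)])]
  masks <- lapply(keep, function(k) matrix(as.integer(lab == k), nrow(pixels)))
  mask_set(masks)
}

#' Mask providers
#'
#' A mask provider is any function mapping a grayscale pixel matrix to a
#' [mask_set()]. `toy_provider()` wraps [toy_segment()]; `fixed_provider()`
#' always returns the given masks (useful for testing and for adapting
#' external segmenters whose output is precomputed). An adapter for a
#' promptable foundation segmenter (e.g. a pretrained "vit_h" checkpoint)
#' can be plugged in through the same contract; it is not bundled because it
#' requires an external weight download.
#'
#' @param min_area Passed to [toy_segment()].
#' @return A function `pixels -> mask_set`.
#' @export
toy_provider <- function(min_area = 50) {
  function(pixels) toy_segment(pixels, min_area = min_area)
}

#' @rdname toy_provider
#' @param masks A list of binary masks returned verbatim for every image.
#' @export
fixed_provider <- function(masks) {
  force(masks)
  function(pixels) mask_set(masks)
}

#' Apply a mask provider across a cohort
#'
#' Runs the provider on every image, preserving order. A provider failure on
#' an individual image is logged as a warning and yields an empty mask set;
#' only a provider that fails on every image aborts the batch.
#'
#' @param images Cohort tibble with a `pixels` list-column.
#' @param provider A mask provider function (see [toy_provider()]).
#' @return The input tibble with an added `masks` list-column of `mask_set`s.
#' @export
apply_mask_provider <- function(images, provider = toy_provider()) {
  stopifnot(is.data.frame(images), "pixels" %in% names(images))
  n_fail <- 0L
  masks <- purrr::map2(images$pixels, images$image_id, function(px, id) {
    tryCatch(provider(px), error = function(e) {
      n_fail <<- n_fail + 1L
      warn(sprintf("Mask provider failed on image %s: %s", id,
                   conditionMessage(e)))
      mask_set()
    })
  })
  if (n_fail == nrow(images) && nrow(images) > 0) {
    stop_ctrender("Mask provider failed on every image.",
                  class = "ctrender_provider_error")
  }
  images$masks <- masks
  images
}

#' Overlay rendering specification
#'
#' The overlay keeps the underlying tissue visible: opacity is capped at 0.5
#' (transparency of at least 50 percent) so the segmented region and the
#' anatomy it belongs to are displayed simultaneously.
#'
#' @param alpha Overlay opacity in `[0, 0.5]`.
#' @param palette Character vector of hex colors cycled across masks.
#' @return An `overlay_spec` object.
#' @export
overlay_spec <- function(alpha = 0.5,
                         palette = c("#FF0000", "#00FF00", "#0000FF",
                                     "#FFFF00", "#FF00FF", "#00FFFF")) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 0.5) {
    stop_ctrender("`alpha` must lie in [0, 0.5] (>= 50% transparency).",
                  class = "ctrender_contract_error")
  }
  structure(list(alpha = alpha,
                 palette = t(grDevices::col2rgb(palette))),
            class = "overlay_spec")
}

#' Alpha-blend region masks over a grayscale image
#'
#' Inside each mask the output is
#' `round(alpha * color + (1 - alpha) * base)` per channel (rounding half
#' away from zero, clipped to `[0, 255]`); the palette is cycled by mask
#' index and later masks overwrite earlier ones where they overlap. Pixels
#' outside all masks are the base value replicated to RGB.
#'
#' @param pixels Grayscale matrix in `[0, 255]`.
#' @param masks A [mask_set()] whose masks match `dim(pixels)`.
#' @param spec An [overlay_spec()].
#' @return An integer array `H x W x 3`.
#' @export
blend_overlay <- function(pixels, masks, spec = overlay_spec()) {
  stopifnot(is.matrix(pixels), inherits(masks, "mask_set"),
            inherits(spec, "overlay_spec"))
  for (m in masks$masks) {
    if (!identical(dim(m), dim(pixels))) {
      stop_ctrender("Mask dimensions do not match the image.",
                    class = "ctrender_dim_error")
    }
  }
  H <- nrow(pixels); W <- ncol(pixels)
  out <- array(rep(as.numeric(pixels), 3), c(H, W, 3))
  a <- spec$alpha
  npal <- nrow(spec$palette)
  for (i in seq_along(masks$masks)) {
    sel <- masks$masks[[i]] == 1
    col <- spec$palette[(i - 1L) %% npal + 1L, ]
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- a * col[ch] + (1 - a) * pixels[sel]
      out[, , ch] <- plane
    }
  }
  out <- round_half_up(pmin(pmax(out, 0), 255))
  storage.mode(out) <- "integer"
  out
}

#' Segment and overlay a whole cohort
#'
#' Convenience wrapper for pipeline step one: apply a mask provider and blend
#' the resulting masks over every slice.
#'
#' @inheritParams apply_mask_provider
#' @param spec An [overlay_spec()].
#' @return The cohort tibble with `masks` and `overlay` list-columns.
#' @export
segment_overlay_cohort <- function(images, provider = toy_provider(),
                                   spec = overlay_spec()) {
  images <- apply_mask_provider(images, provider)
  images$overlay <- purrr::map2(images$pixels, images$masks,
                                function(px, ms) blend_overlay(px, ms, spec))
  images
}
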