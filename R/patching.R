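#' Extract nonoverlapping tumor patches from an annotated slide
#'
#' Tiles the slide on a grid anchored at pixel (0, 0) with nonoverlapping
#' `patch_size` x `patch_size` tiles (remainder margins discarded), keeps a
#' tile iff its annotation-mask coverage reaches `coverage_threshold`, and
#' returns tiles in deterministic row-major order. Coordinates are 0-based
#' top-left corners with half-open spans, the convention heatmap
#' reconstruction relies on.
#'
#' @param slide A `synthetic_slide`, or a height x width x 3 RGB array.
#' @param mask Binary (0/1) matrix of the annotated tumor region; taken from
#'   the slide if a `synthetic_slide` is given.
#' @param patch_size Tile side in pixels.
#' @param coverage_threshold Minimum fraction of tile pixels inside the
#'   mask.
#' @param slide_id Identifier recorded in the manifest.
#' @param keep_pixels If `FALSE`, only the manifest is returned (tiles can
#'   be re-cut later); saves memory when streaming many slides.
#' @return Object of class `patch_set`: list with `manifest` (data.frame:
#'   `slide_id`, `row`, `col`, `coverage`, `label`) and `tiles` (list of
#'   RGB arrays, or `NULL`).
#' @export
extract_patches <- function(slide, mask = NULL, patch_size = 512L,
                            coverage_threshold = 0.75, slide_id = "slide",
                            keep_pixels = TRUE) {
  if (inherits(slide, "synthetic_slide")) {
    if (is.null(mask)) mask <- slide$annotation_mask
    image <- slide$image
  } else {
    image <- slide
  }
  if (is.null(mask)) stop("mask is required", call. = FALSE)
  if (nrow(mask) != dim(image)[1] || ncol(mask) != dim(image)[2]) {
    stop("slide and mask dimensions differ", call. = FALSE)
  }
  patch_size <- as.integer(patch_size)
  n_r <- nrow(mask) %/% patch_size
  n_c <- ncol(mask) %/% patch_size
  rows <- integer(0); cols <- integer(0); covs <- numeric(0)
  tiles <- if (keep_pixels) list() else NULL
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_c)) {
      r0 <- (i - 1L) * patch_size
      c0 <- (j - 1L) * patch_size
      cov <- mean(mask[r0 + seq_len(patch_size), c0 + seq_len(patch_size)])
      if (cov >= coverage_threshold) {
        rows <- c(rows, r0); cols <- c(cols, c0); covs <- c(covs, cov)
        if (keep_pixels) {
          tiles[[length(tiles) + 1L]] <-
            image[r0 + seq_len(patch_size), c0 + seq_len(patch_size), , drop = FALSE]
        }
      }
    }
  }
  manifest <- data.frame(slide_id = rep(slide_id, length(rows)),
                         row = rows, col = cols, coverage = covs,
                         label = rep(NA_character_, length(rows)),
                         stringsAsFactors = FALSE)
  structure(list(manifest = manifest, tiles = tiles,
                 patch_size = patch_size,
                 slide_dims = c(nrow(mask), ncol(mask))),
            class = "patch_set")
}

#' Propagate a slide-level class label to every patch
#'
#' All patches extracted from a slide inherit the slide's own label — the
#' weak-labelling scheme that makes patch labels inherently noisy in
#' admixed tumors.
#'
#' @param patches A `patch_set`.
#' @param slide_label Either `"LumA"` or `"nonLumA"`.
#' @return The `patch_set` with every manifest row labelled.
#' @export
label_patches <- function(patches, slide_label) {
  if (!slide_label %in% c("LumA", "nonLumA")) {
    stop('slide_label must be "LumA" or "nonLumA"', call. = FALSE)
  }
  patches$manifest$label <- rep(slide_label, nrow(patches$manifest))
  patches
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("Patch set: %d patches of %d px from %s (%s pixels kept)\n",
              nrow(x$manifest), x$patch_size,
              paste(unique(x$manifest$slide_id), collapse = ","),
              if (is.null(x$tiles)) "no" else "with"))
  invisible(x)
}

#' Summary texture features of one patch
#'
#' Deterministic per-tile descriptors that carry the texture cues the
#' synthetic slides encode (nucleus density, size and stain darkness):
#' channel means, luminance moments, dark-pixel fractions at three
#' thresholds, gradient energies, coarse block-level contrast and a
#' hematoxylin-purple balance term.
#'
#' @param tile height x width x 3 RGB array in \[0,1\].
#' @return Named numeric vector of 12 features.
#' @export
patch_features <- function(tile) {
  g <- 0.299 * tile[, , 1] + 0.587 * tile[, , 2] + 0.114 * tile[, , 3]
  blk <- block_means(g, 32L)
  c(mean_r = mean(tile[, , 1]), mean_g = mean(tile[, , 2]),
    mean_b = mean(tile[, , 3]),
    mean_lum = mean(g), sd_lum = stats::sd(g),
    dark50 = mean(g < 0.50), dark65 = mean(g < 0.65), dark80 = mean(g < 0.80),
    grad_r = mean(abs(diff(g))), grad_c = mean(abs(t(diff(t(g))))),
    block_sd = stats::sd(blk),
    purple = mean(tile[, , 3] - tile[, , 2]))
}

# Means over non-overlapping b x b blocks (trailing remainder discarded).
block_means <- function(g, b) {
  nr <- nrow(g) %/% b; nc <- ncol(g) %/% b
  g <- g[seq_len(nr * b), seq_len(nc * b), drop = FALSE]
  M <- matrix(colMeans(matrix(g, nrow = b)), nrow = nr)   # nr x (nc*b)
  t(matrix(colMeans(matrix(t(M), nrow = b)), nrow = nc))  # nr x nc
}

#' Feature matrix for all patches in a set
#'
#' @param patches A `patch_set` with pixels kept.
#' @return Numeric matrix, one row per patch, columns as in
#'   [patch_features()].
#' @export
featurize_patches <- function(patches) {
  if (is.null(patches$tiles)) stop("patch_set has no pixel tiles", call. = FALSE)
  t(vapply(patches$tiles, patch_features, numeric(12L)))
}
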