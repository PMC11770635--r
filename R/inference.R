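#' Per-patch LumA probabilities from a trained checkpoint
#'
#' @param model A `luma_checkpoint` from [train_classifier()] /
#'   [select_model()].
#' @param patches A `patch_set` with pixels kept, or a precomputed feature
#'   matrix with the same columns the model was trained on.
#' @return Numeric vector of probabilities in \[0, 1\], one per patch, in
#'   input order; deterministic for a fixed checkpoint.
#' @export
classify_patches <- function(model, patches) {
  if (!inherits(model, "luma_checkpoint")) {
    stop("model must be a luma_checkpoint", call. = FALSE)
  }
  feats <- if (inherits(patches, "patch_set")) featurize_patches(patches) else patches
  if (!is.matrix(feats) || ncol(feats) != length(model$center)) {
    stop("patch features do not match the model input size", call. = FALSE)
  }
  X <- sweep(sweep(feats, 2L, model$center, "-"), 2L, model$scale, "/")
  mlp_forward(model$model_state, X)
}

#' @rdname classify_patches
#' @param object,newdata,... standard predict arguments.
#' @export
predict.luma_checkpoint <- function(object, newdata, ...) {
  classify_patches(object, newdata)
}

#' Slide-level iLumA% and pure/admixed call
#'
#' iLumA% is the percentage of a slide's tumor patches whose predicted LumA
#' probability strictly exceeds the threshold. The case is called `pure`
#' iff a strict majority of patches is classified LumA (iLumA% > 50);
#' exactly 50% is `admixed`.
#'
#' @param probabilities Per-patch LumA probabilities (nonempty).
#' @param threshold Classification threshold, default 0.5.
#' @param slide_id Identifier for the output row.
#' @return One-row data.frame of class `slide_score`: `slide_id`,
#'   `n_patches`, `iluma_pct`, `call`.
#' @export
slide_iluma <- function(probabilities, threshold = 0.5, slide_id = "slide") {
  if (!length(probabilities)) stop("no patch probabilities given", call. = FALSE)
  if (any(!is.finite(probabilities))) stop("probabilities must be finite", call. = FALSE)
  pct <- 100 * mean(probabilities > threshold)
  out <- data.frame(slide_id = slide_id,
                    n_patches = length(probabilities),
                    iluma_pct = pct,
                    call = if (pct > 50) "pure" else "admixed",
                    stringsAsFactors = FALSE)
  class(out) <- c("slide_score", "data.frame")
  out
}

#' Spatial heterogeneity heatmap from patch probabilities
#'
#' Each scored tile region is filled with its LumA probability on the patch
#' grid, smoothed with an isotropic 2D Gaussian (SD in patch-grid units,
#' reflective boundary), and upsampled back to slide resolution. Tiles
#' without a score (outside the annotation, or discarded margins) are
#' missing (`NA`) and excluded from the smoothing support via normalized
#' convolution — they are never imputed as probability 0.
#'
#' @param patch_coords data.frame with 0-based `row`, `col` top-left pixel
#'   coordinates of scored tiles (multiples of `patch_size`), e.g. a
#'   `patch_set` manifest.
#' @param probabilities One probability per coordinate row.
#' @param slide_dims Integer `c(height, width)` of the source slide.
#' @param patch_size Tile side in pixels.
#' @param sigma Gaussian SD in patch-grid units (one cell = one patch).
#' @return Object of class `luma_heatmap`: list with `values` (height x
#'   width matrix in \[0,1\] with `NA` where unscored), `grid` (smoothed
#'   patch-grid matrix), `sigma`.
#' @export
build_heatmap <- function(patch_coords, probabilities, slide_dims,
                          patch_size = 512L, sigma = 2.5) {
  stopifnot(nrow(patch_coords) == length(probabilities))
  gh <- slide_dims[1] %/% patch_size
  gw <- slide_dims[2] %/% patch_size
  gi <- patch_coords$row %/% patch_size + 1L
  gj <- patch_coords$col %/% patch_size + 1L
  if (any(patch_coords$row %% patch_size != 0) ||
      any(patch_coords$col %% patch_size != 0)) {
    stop("patch coordinates must be multiples of patch_size", call. = FALSE)
  }
  if (any(gi < 1 | gi > gh | gj < 1 | gj > gw)) {
    stop("patch coordinate outside slide dimensions", call. = FALSE)
  }
  grid <- matrix(NA_real_, gh, gw)
  grid[cbind(gi, gj)] <- probabilities
  sm <- gaussian_smooth_na(grid, sigma)
  # upsample grid cells to pixel blocks; remainder margins stay NA
  values <- matrix(NA_real_, slide_dims[1], slide_dims[2])
  ridx <- rep(seq_len(gh), each = patch_size)
  cidx <- rep(seq_len(gw), each = patch_size)
  values[seq_along(ridx), seq_along(cidx)] <- sm[ridx, cidx]
  structure(list(values = values, grid = sm, sigma = sigma,
                 patch_size = patch_size),
            class = "luma_heatmap")
}

# Isotropic Gaussian smoothing with reflective boundary and NA-aware
# normalized convolution: conv(v * m) / conv(m) over the scored support m.
gaussian_smooth_na <- function(grid, sigma) {
  if (sigma <= 0) return(grid)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- stats::dnorm(-r:r, sd = sigma)
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  m <- !is.na(grid)
  v <- grid
  v[!m] <- 0
  num <- conv2_reflect(v, kern)
  den <- conv2_reflect(m * 1, kern)
  out <- num / den
  out[!m] <- NA_real_
  out[m] <- pmin(1, pmax(0, out[m]))
  out
}

# Direct 2D convolution with reflective (mirror) boundary handling; grids
# are patch-scale (tens of cells), so the direct loop is cheap.
conv2_reflect <- function(x, kern) {
  r <- (nrow(kern) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  ri <- reflect_index(seq(1 - r, n + r), n)
  ci <- reflect_index(seq(1 - r, m + r), m)
  xp <- x[ri, ci, drop = FALSE]
  out <- matrix(0, n, m)
  for (dy in 0:(2 * r)) {
    for (dx in 0:(2 * r)) {
      out <- out + kern[dy + 1L, dx + 1L] *
        xp[dy + seq_len(n), dx + seq_len(m), drop = FALSE]
    }
  }
  out
}

# Mirror indices into 1..n using half-sample symmetric reflection
# (...x2 x1 | x1 x2 ... xn | xn ...). This reflective convention conserves
# the raster sum under a symmetric normalized kernel.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- (i - 1L) %% period
  j <- ifelse(j < 0, j + period, j)
  as.integer(ifelse(j < n, j + 1L, period - j))
}

#' @export
print.luma_heatmap <- function(x, ...) {
  cat(sprintf("Heatmap %d x %d px (grid %d x %d, sigma %.2f patch units); ",
              nrow(x$values), ncol(x$values), nrow(x$grid), ncol(x$grid),
              x$sigma))
  cat(sprintf("%d scored cells\n", sum(!is.na(x$grid))))
  invisible(x)
}

#' Plot a heterogeneity heatmap
#'
#' @param x A `luma_heatmap`.
#' @param y Unused.
#' @param ... Passed to [graphics::image()].
#' @export
plot.luma_heatmap <- function(x, y, ...) {
  g <- t(x$grid)[, rev(seq_len(nrow(x$grid))), drop = FALSE]
  graphics::image(g, zlim = c(0, 1), useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  axes = FALSE, ...)
  invisible(x)
}

#' Write a heatmap overlay PNG
#'
#' Blends the probability raster (blue = non-LumA, red = LumA) onto the
#' slide image; unscored pixels keep the original image.
#'
#' @param heatmap A `luma_heatmap`.
#' @param image RGB array of the source slide.
#' @param path Output PNG path.
#' @param alpha Overlay opacity.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, image, path, alpha = 0.45) {
  v <- heatmap$values
  ok <- !is.na(v)
  out <- image
  red <- v; blue <- 1 - v
  for (ch in 1:3) {
    plane <- image[, , ch]
    col <- switch(ch, red, v * 0 + 0.2, blue)
    plane[ok] <- (1 - alpha) * plane[ok] + alpha * col[ok]
    out[, , ch] <- plane
  }
  png::writePNG(out, path)
  invisible(path)
}
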