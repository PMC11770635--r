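#' Default per-subtype texture parameters
#'
#' Texture knobs standing in for subtype morphology: nucleus density (nuclei
#' per 100 x 100 px), nucleus radius (px) and stain darkness (0-1 mixing
#' weight towards hematoxylin purple). LumA territory is rendered sparser and
#' lighter than the three non-LumA subtypes, so local texture statistics carry
#' the locally dominant subtype.
#'
#' @return Named list of per-subtype lists with `density`, `radius`,
#'   `darkness`.
#' @export
default_textures <- function() {
  list(
    LumA  = list(density = 4,  radius = 3, darkness = 0.50),
    LumB  = list(density = 8,  radius = 4, darkness = 0.75),
    HER2  = list(density = 6,  radius = 6, darkness = 0.80),
    Basal = list(density = 11, radius = 4, darkness = 0.90)
  )
}

# Superellipse tumor mask: contiguous, covers most of the frame.
tumor_mask <- function(height, width, a = 0.49, exponent = 6) {
  y <- (seq_len(height) - (height + 1) / 2) / (a * height)
  x <- (seq_len(width) - (width + 1) / 2) / (a * width)
  m <- outer(abs(y)^exponent, abs(x)^exponent, "+") <= 1
  storage.mode(m) <- "integer"
  m
}

# Voronoi label field on a coarse grid, greedily rebalanced so per-subtype
# mask-area fractions track the requested proportions.
voronoi_labels <- function(proportions, height, width, mask, n_regions,
                           stride = 4L, area_tol = 0.02) {
  ch <- as.integer(ceiling(height / stride))
  cw <- as.integer(ceiling(width / stride))
  sy <- runif(n_regions, 1, ch)
  sx <- runif(n_regions, 1, cw)
  best <- matrix(Inf, ch, cw)
  cell <- matrix(0L, ch, cw)
  ys <- seq_len(ch)
  xs <- seq_len(cw)
  for (r in seq_len(n_regions)) {
    d <- outer((ys - sy[r])^2, (xs - sx[r])^2, "+")
    upd <- d < best
    best[upd] <- d[upd]
    cell[upd] <- r
  }
  # initial labels: largest-remainder apportionment of regions to subtypes
  counts <- apportion(proportions, n_regions)
  lab_of_region <- sample(rep.int(seq_len(4L), counts))
  # upsample region ids to full resolution, then rebalance on mask areas
  region_full <- cell[rep(seq_len(ch), each = stride)[seq_len(height)],
                      rep(seq_len(cw), each = stride)[seq_len(width)]]
  inside <- mask == 1L
  region_areas <- tabulate(region_full[inside], nbins = n_regions)
  total <- sum(region_areas)
  target <- proportions * total
  current <- vapply(seq_len(4L), function(k) {
    sum(region_areas[lab_of_region == k])
  }, numeric(1))
  for (it in seq_len(10L * n_regions)) {
    dev <- current - target
    if (max(abs(dev)) / total <= area_tol) break
    k_over <- which.max(dev)
    k_under <- which.min(dev)
    cand <- which(lab_of_region == k_over & region_areas > 0)
    if (!length(cand)) break
    ideal <- min(dev[k_over], -dev[k_under])
    r <- cand[which.min(abs(region_areas[cand] - ideal))]
    if (region_areas[r] >= 2 * ideal) {
      # moving this region would overshoot more than it helps
      smaller <- cand[region_areas[cand] < 2 * ideal]
      if (length(smaller)) r <- smaller[which.max(region_areas[smaller])]
    }
    lab_of_region[r] <- k_under
    current[k_over] <- current[k_over] - region_areas[r]
    current[k_under] <- current[k_under] + region_areas[r]
  }
  lab_full <- matrix(lab_of_region[region_full], height, width)
  lab_full[!inside] <- 0L
  lab_full
}

#' Render a synthetic annotated tumor slide
#'
#' Produces an RGB image whose tumor region is partitioned into contiguous
#' Voronoi territories, one intrinsic subtype per territory, with territory
#' areas matching the case's admixture proportions; each territory is
#' textured with nuclei drawn at that subtype's density, radius and stain
#' darkness. A stand-in for an annotated H&E whole-slide image with known
#' per-pixel subtype ground truth.
#'
#' @param admixture Numeric 4-vector of subtype proportions (LumA, LumB,
#'   HER2, Basal order), or a row of a `true_admixture` data.frame.
#' @param height,width Image dimensions in pixels.
#' @param texture_params Per-subtype texture list, see [default_textures()].
#' @param seed Integer seed; rasters are bitwise reproducible.
#' @param n_regions Number of Voronoi territories.
#' @param mpp Microns per pixel, carried as metadata.
#' @return Object of class `synthetic_slide`: list with `image`
#'   (height x width x 3 array in \[0,1\]), `annotation_mask` (0/1 integer
#'   matrix), `subtype_map` (integer matrix, 0 outside the mask, 1-4 =
#'   subtype index inside) and `mpp`.
#' @examples
#' sl <- generate_slide(c(0.7, 0.1, 0.1, 0.1), 256, 256, seed = 1)
#' mean(sl$annotation_mask)
#' @export
generate_slide <- function(admixture, height = 1536, width = 1536,
                           texture_params = default_textures(), seed = 1,
                           n_regions = 64, mpp = 0.25) {
  if (is.data.frame(admixture)) {
    admixture <- as.numeric(admixture[1, paste0("p", SUBTYPES)])
  }
  admixture <- as.numeric(admixture)
  if (length(admixture) != 4L || any(!is.finite(admixture)) ||
      any(admixture < 0)) {
    stop("admixture must be a finite nonnegative 4-vector", call. = FALSE)
  }
  if (abs(sum(admixture) - 1) > 1e-6) {
    stop("admixture proportions must sum to 1", call. = FALSE)
  }
  height <- as.integer(height); width <- as.integer(width)
  with_seed(seed, {
    mask <- tumor_mask(height, width)
    smap <- voronoi_labels(admixture, height, width, mask, n_regions)
    img <- render_texture(smap, mask, texture_params)
    structure(list(image = img, annotation_mask = mask, subtype_map = smap,
                   mpp = mpp),
              class = "synthetic_slide")
  })
}

# Draw background + per-subtype nuclei into an RGB array.
render_texture <- function(smap, mask, texture_params) {
  h <- nrow(smap); w <- ncol(smap)
  stain <- runif(1, 0.95, 1.05)  # per-slide global stain intensity
  base <- c(0.91, 0.86, 0.90) * stain
  dark <- c(0.28, 0.16, 0.42)
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) {
    img[, , ch] <- pmin(1, pmax(0, base[ch] + rnorm(h * w, sd = 0.02)))
  }
  outside <- mask == 0L
  if (any(outside)) {
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[outside] <- pmin(1, plane[outside] + 0.06)
      img[, , ch] <- plane
    }
  }
  for (k in seq_along(SUBTYPES)) {
    tp <- texture_params[[SUBTYPES[k]]]
    px <- which(smap == k)
    if (!length(px)) next
    n_nuc <- round(tp$density * length(px) / 1e4)
    if (n_nuc < 1) next
    centers <- sample(px, n_nuc, replace = TRUE)
    rows <- (centers - 1L) %% h + 1L
    cols <- (centers - 1L) %/% h + 1L
    radii <- pmax(1, tp$radius * runif(n_nuc, 0.7, 1.3))
    for (i in seq_len(n_nuc)) {
      r <- radii[i]; ri <- ceiling(r)
      y0 <- max(1L, rows[i] - ri); y1 <- min(h, rows[i] + ri)
      x0 <- max(1L, cols[i] - ri); x1 <- min(w, cols[i] + ri)
      dy <- (y0:y1) - rows[i]; dx <- (x0:x1) - cols[i]
      disk <- outer(dy^2, dx^2, "+") <= r^2
      wgt <- tp$darkness * runif(1, 0.85, 1.15)
      wgt <- min(wgt, 1)
      for (ch in 1:3) {
        blk <- img[y0:y1, x0:x1, ch]
        blk[disk] <- blk[disk] * (1 - wgt) + dark[ch] * wgt
        img[y0:y1, x0:x1, ch] <- blk
      }
    }
  }
  img
}
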