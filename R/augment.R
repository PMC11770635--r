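# Patch augmentation: color jitter, 90-degree rotations, flips and random
# elastic deformations. All operate on height x width x 3 arrays in [0,1].

#' Rotate a tile by 90 degrees counterclockwise
#'
#' @param tile RGB array.
#' @param k Number of quarter turns.
#' @return Rotated tile; four turns recover the original exactly.
#' @export
rotate90 <- function(tile, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    tile <- aperm(tile, c(2, 1, 3))[dim(tile)[2]:1, , , drop = FALSE]
  }
  tile
}

flip_tile <- function(tile, horizontal = TRUE) {
  if (horizontal) tile[, dim(tile)[2]:1, , drop = FALSE]
  else tile[dim(tile)[1]:1, , , drop = FALSE]
}

color_jitter <- function(tile, amount = 0.1) {
  scale <- runif(3, 1 - amount, 1 + amount)
  shift <- runif(3, -amount / 2, amount / 2)
  for (ch in 1:3) tile[, , ch] <- tile[, , ch] * scale[ch] + shift[ch]
  tile[] <- pmin(1, pmax(0, tile))   # pmax(0, .) would drop the dims
  tile
}

# Random elastic deformation: a coarse displacement grid, bilinearly
# upsampled, applied with nearest-pixel resampling and edge clamping.
elastic_deform <- function(tile, amplitude = 8, grid = 6L) {
  h <- dim(tile)[1]; w <- dim(tile)[2]
  dy <- matrix(runif(grid^2, -amplitude, amplitude), grid, grid)
  dx <- matrix(runif(grid^2, -amplitude, amplitude), grid, grid)
  up <- function(d) {
    # bilinear upsample grid x grid -> h x w
    yi <- seq(1, grid, length.out = h)
    xi <- seq(1, grid, length.out = w)
    y0 <- pmin(floor(yi), grid - 1L); x0 <- pmin(floor(xi), grid - 1L)
    fy <- yi - y0; fx <- xi - x0
    a <- d[cbind(rep(y0, w), rep(x0, each = h))]
    b <- d[cbind(rep(y0 + 1, w), rep(x0, each = h))]
    cc <- d[cbind(rep(y0, w), rep(x0 + 1, each = h))]
    dd <- d[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
    fym <- rep(fy, w); fxm <- rep(fx, each = h)
    matrix(a * (1 - fym) * (1 - fxm) + b * fym * (1 - fxm) +
             cc * (1 - fym) * fxm + dd * fym * fxm, h, w)
  }
  sy <- pmin(pmax(round(row(matrix(0, h, w)) + up(dy)), 1), h)
  sx <- pmin(pmax(round(col(matrix(0, h, w)) + up(dx)), 1), w)
  idx <- cbind(as.vector(sy), as.vector(sx))
  out <- tile
  for (ch in 1:3) {
    plane <- tile[, , ch]
    out[, , ch] <- matrix(plane[idx], h, w)
  }
  out
}

#' Randomly augment a patch
#'
#' Applies the enabled operations (flips, 90-degree rotations, color jitter,
#' elastic deformation) with parameters drawn from the seeded RNG. The tile
#' keeps its dimensions and its label; with all toggles off the tile is
#' returned unchanged; a fixed seed gives identical output.
#'
#' @param tile RGB array (or a single-patch `patch_set` tile).
#' @param ops Named logical toggles: `flip`, `rotate`, `jitter`, `elastic`.
#' @param seed Integer seed.
#' @param jitter_amount,elastic_amplitude Strengths of the stochastic ops.
#' @return Augmented tile of identical dimensions.
#' @export
augment <- function(tile, ops = list(flip = TRUE, rotate = TRUE,
                                     jitter = TRUE, elastic = TRUE),
                    seed = 1L, jitter_amount = 0.1, elastic_amplitude = 8) {
  with_seed(seed, {
    if (isTRUE(ops$flip)) {
      if (runif(1) < 0.5) tile <- flip_tile(tile, horizontal = TRUE)
      if (runif(1) < 0.5) tile <- flip_tile(tile, horizontal = FALSE)
    }
    if (isTRUE(ops$rotate)) tile <- rotate90(tile, sample(0:3, 1))
    if (isTRUE(ops$jitter)) tile <- color_jitter(tile, jitter_amount)
    if (isTRUE(ops$elastic)) tile <- elastic_deform(tile, elastic_amplitude)
    tile
  })
}
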