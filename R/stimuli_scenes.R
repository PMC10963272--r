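# Synthetic factorized scenes: the model's stand-in for a disentangled
# 3D-scene dataset. Each scene is determined by six generative factors
# (floor hue, wall hue, object hue, object shape, scale, orientation) and is
# rendered deterministically as a 64 x 64 x 3 image: a wall band above a
# floor band, with a single coloured object centred on the floor whose
# silhouette identifies its shape class and whose rendered height grows
# monotonically with the scale factor.

SCENE_DIM <- c(64L, 64L, 3L)
SCENE_SHAPES <- c("cube", "cylinder", "sphere", "capsule")
HORIZON_ROW <- 42L   # rows 1..42 wall, 43..64 floor
OBJECT_BASE_ROW <- 58L

#' Construct scene generative factors
#'
#' @param floor_hue,wall_hue,object_hue Hue fractions in `[0, 1)`.
#' @param shape One of `"cube"`, `"cylinder"`, `"sphere"`, `"capsule"`.
#' @param scale Object size fraction in `(0, 1]`.
#' @param orientation Signed fraction in `[-1, 1]`; horizontal offset proxy.
#' @return An object of class `scene_factors`.
#' @export
scene_factors <- function(floor_hue, wall_hue, object_hue, shape, scale,
                          orientation = 0) {
  shape <- match.arg(shape, SCENE_SHAPES)
  for (h in c(floor_hue, wall_hue, object_hue)) {
    if (!is.numeric(h) || h < 0 || h >= 1) stop("hues must lie in [0, 1)")
  }
  if (!is.numeric(scale) || scale <= 0 || scale > 1) {
    stop("`scale` must lie in (0, 1]")
  }
  if (!is.numeric(orientation) || abs(orientation) > 1) {
    stop("`orientation` must lie in [-1, 1]")
  }
  structure(list(floor_hue = floor_hue, wall_hue = wall_hue,
                 object_hue = object_hue, shape = shape, scale = scale,
                 orientation = orientation),
            class = "scene_factors")
}

#' Sample scene factors uniformly
#'
#' Factors are drawn uniformly over their ranges; the shape is uniform over
#' the four categories.
#'
#' @param n Number of factor sets to draw.
#' @param seed Optional integer seed.
#' @return A list of [scene_factors()] objects (a single object if `n = 1`
#'   and `simplify = TRUE`).
#' @param simplify Return the bare object rather than a length-1 list when
#'   `n = 1`.
#' @export
sample_factors <- function(n = 1L, seed = NULL, simplify = TRUE) {
  use_seed(seed)
  out <- replicate(n, scene_factors(
    floor_hue = stats::runif(1L, 0, 1 - 1e-9),
    wall_hue = stats::runif(1L, 0, 1 - 1e-9),
    object_hue = stats::runif(1L, 0, 1 - 1e-9),
    shape = sample(SCENE_SHAPES, 1L),
    scale = stats::runif(1L, 0.45, 0.95),
    orientation = stats::runif(1L, -1, 1)
  ), simplify = FALSE)
  if (n == 1L && simplify) out[[1L]] else out
}

# Hue -> RGB through an isoluminant colour wheel: channel c gets
# 0.5 + 0.4 * cos(2*pi*(hue + phase_c)) with phases 120 degrees apart. Two
# exact consequences: (1) every pixel's channel sum (1.5) and squared norm
# (0.99) are hue-invariant, so all rendered scenes have identical flat-vector
# sums and norms and noise-driven Hopfield replay samples stored scenes
# approximately uniformly instead of favouring bright memories; (2) all
# values lie in [0.1, 0.9], strictly positive, so the extended model's
# "overwrite with non-zero stored sensory features" rule is exact.
scene_rgb <- function(hue, amp = 0.4) {
  0.5 + amp * cos(2 * pi * (hue + c(0, 1 / 3, 2 / 3)))
}

object_silhouette <- function(shape, height) {
  # Returns a logical mask (height rows x width cols) of the object seen
  # front-on; width depends on the shape so the four classes are linearly
  # separable from pixels.
  h <- max(3L, as.integer(height))
  switch(shape,
    cube = matrix(TRUE, h, h),
    cylinder = {
      w <- max(3L, round(0.55 * h))
      matrix(TRUE, h, w)
    },
    sphere = {
      r <- h / 2
      cy <- (h + 1) / 2
      d <- outer(seq_len(h) - cy, seq_len(h) - cy,
                 function(y, x) sqrt(x^2 + y^2))
      d <= r
    },
    capsule = {
      w <- max(3L, round(0.35 * h))
      r <- w / 2
      cx <- (w + 1) / 2
      m <- matrix(TRUE, h, w)
      for (row in seq_len(h)) {
        dy <- if (row <= r) r - row + 0.5 else if (row > h - r) row - (h - r) - 0.5 else 0
        if (dy > 0) {
          dx <- abs(seq_len(w) - cx)
          m[row, ] <- sqrt(dx^2 + dy^2) <= r
        }
      }
      m
    })
}

#' Render a factorized scene
#'
#' Deterministic given the factors: the upper band takes the wall colour, the
#' lower band the floor colour, and a single object of the object colour is
#' drawn centred near the horizontal midline. The object's rendered height is
#' `6 + round(40 * scale)` pixels, strictly monotone in `scale` at the
#' resolution of rounding.
#'
#' @param factors A [scene_factors()] object.
#' @return A 64 x 64 x 3 array with values in `[0.1, 0.9]`.
#' @export
render_scene <- function(factors) {
  stopifnot(inherits(factors, "scene_factors"))
  img <- array(0, SCENE_DIM)
  wall <- scene_rgb(factors$wall_hue)
  floor <- scene_rgb(factors$floor_hue)
  obj <- scene_rgb(factors$object_hue)
  for (ch in 1:3) {
    img[seq_len(HORIZON_ROW), , ch] <- wall[ch]
    img[(HORIZON_ROW + 1L):64L, , ch] <- floor[ch]
  }
  h <- 6L + as.integer(round(40 * factors$scale))
  mask <- object_silhouette(factors$shape, h)
  rows <- (OBJECT_BASE_ROW - nrow(mask) + 1L):OBJECT_BASE_ROW
  cx <- 32L + as.integer(round(6 * factors$orientation))
  cols <- cx - floor((ncol(mask) - 1L) / 2) + seq_len(ncol(mask)) - 1L
  keep_r <- rows >= 1L & rows <= 64L
  keep_c <- cols >= 1L & cols <= 64L
  mask <- mask[keep_r, keep_c, drop = FALSE]
  rows <- rows[keep_r]; cols <- cols[keep_c]
  for (ch in 1:3) {
    plane <- img[rows, cols, ch]
    plane[mask] <- obj[ch]
    img[rows, cols, ch] <- plane
  }
  img
}

#' Exact object-pixel mask of a rendered scene
#'
#' Recomputes which pixels of [render_scene()] belong to the central object,
#' by exact colour match against the object colour. Used by size oracles.
#'
#' @param factors A [scene_factors()] object.
#' @return A 64 x 64 logical matrix.
#' @export
scene_object_mask <- function(factors) {
  img <- render_scene(factors)
  obj <- scene_rgb(factors$object_hue)
  abs(img[, , 1] - obj[1]) < 1e-12 &
    abs(img[, , 2] - obj[2]) < 1e-12 &
    abs(img[, , 3] - obj[3]) < 1e-12
}

#' Construct a novelty overlay
#'
#' A set of white squares to superimpose on a scene, each with its own
#' opacity; models novel, schema-inconsistent sensory features.
#'
#' @param squares A data frame with columns `row`, `col` (top-left corner),
#'   `side` (pixels) and `opacity` in `(0, 1]`. May have zero rows.
#' @return An object of class `novelty_overlay`.
#' @export
novelty_overlay <- function(squares = data.frame(row = integer(), col = integer(),
                                                 side = integer(),
                                                 opacity = numeric())) {
  stopifnot(is.data.frame(squares),
            all(c("row", "col", "side", "opacity") %in% names(squares)))
  if (nrow(squares) > 0 &&
      (any(squares$opacity <= 0) || any(squares$opacity > 1))) {
    stop("opacities must lie in (0, 1]")
  }
  structure(list(squares = squares), class = "novelty_overlay")
}

#' Sample a random novelty overlay
#'
#' Defaults: 3 squares with sides 4-8 px and opacities 0.4-1.
#'
#' @param n_squares Number of squares.
#' @param side_range,opacity_range Ranges to draw from.
#' @param img_size Image side length in pixels.
#' @param seed Optional integer seed.
#' @return A [novelty_overlay()] object.
#' @export
sample_overlay <- function(n_squares = 3L, side_range = c(4L, 8L),
                           opacity_range = c(0.4, 1), img_size = 64L,
                           seed = NULL) {
  use_seed(seed)
  side <- sample(side_range[1]:side_range[2], n_squares, replace = TRUE)
  novelty_overlay(data.frame(
    row = vapply(side, function(s) sample.int(img_size - s + 1L, 1L), 1L),
    col = vapply(side, function(s) sample.int(img_size - s + 1L, 1L), 1L),
    side = side,
    opacity = stats::runif(n_squares, opacity_range[1], opacity_range[2])
  ))
}

#' Overlay novel white squares on an image
#'
#' Inside each square the output is `(1 - opacity) * image + opacity * 1`;
#' pixels outside all squares are unchanged.
#'
#' @param image An H x W x C array in `[0, 1]`.
#' @param overlay A [novelty_overlay()] object.
#' @return The modified image, clipped to `[0, 1]`.
#' @export
add_novel_features <- function(image, overlay) {
  stopifnot(inherits(overlay, "novelty_overlay"), length(dim(image)) == 3L)
  sq <- overlay$squares
  if (nrow(sq) == 0L) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(sq$row < 1 | sq$col < 1 | sq$row + sq$side - 1 > h |
          sq$col + sq$side - 1 > w)) {
    stop("overlay square out of image bounds")
  }
  for (i in seq_len(nrow(sq))) {
    r <- sq$row[i]:(sq$row[i] + sq$side[i] - 1L)
    cc <- sq$col[i]:(sq$col[i] + sq$side[i] - 1L)
    a <- sq$opacity[i]
    image[r, cc, ] <- (1 - a) * image[r, cc, ] + a
  }
  clip01(image)
}

#' Partially corrupt an image
#'
#' Sets exactly `floor(fraction * N)` scalar values (positions uniform
#' without replacement over all `N = H*W*C` entries) to zero; the noisy-cue
#' transform used throughout recall simulations.
#'
#' @param image An image array.
#' @param fraction Fraction of scalar entries to zero, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The corrupted image.
#' @export
corrupt_partial <- function(image, fraction = 0.1, seed = NULL) {
  stop_if_not_prob(fraction, "fraction")
  use_seed(seed)
  n <- length(image)
  k <- floor(fraction * n)
  if (k > 0) image[sample.int(n, k)] <- 0
  image
}

#' Artificially zoom a scene in or out
#'
#' The margin is `n = round(32 / ratio - 32)` pixels per side: positive `n`
#' (ratio < 1, zoom out) pads the image by replicating edge pixels outwards;
#' negative `n` (ratio > 1, zoom in) crops `|n|` pixels from each side. The
#' result is resized back to 64 x 64 with bilinear interpolation.
#'
#' @param image A 64 x 64 x C array.
#' @param ratio Positive zoom ratio; 1 leaves the image unchanged.
#' @return A 64 x 64 x C array in `[0, 1]`.
#' @export
zoom_view <- function(image, ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0) {
    stop("`ratio` must be a positive number")
  }
  stopifnot(dim(image)[1] == 64L, dim(image)[2] == 64L)
  n <- as.integer(round(32 / ratio - 32))
  if (n == 0L) return(image)
  if (n > 0L) {
    idx <- c(rep(1L, n), 1:64, rep(64L, n))
    big <- image[idx, idx, , drop = FALSE]
  } else {
    keep <- (1L - n):(64L + n)
    big <- image[keep, keep, , drop = FALSE]
  }
  out <- EBImage::resize(big, w = 64L, h = 64L, filter = "bilinear")
  clip01(out)
}

#' Compute the margin implied by a zoom ratio
#'
#' @param ratio Positive zoom ratio.
#' @return Integer margin `n = round(32 / ratio - 32)`.
#' @export
zoom_margin <- function(ratio) as.integer(round(32 / ratio - 32))
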