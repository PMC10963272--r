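# Digit-like glyphs: 28 x 28 x 1 stroke-drawn digits in 10 classes with
# per-sample jitter, standing in for a handwritten-digit dataset in the
# prototypicality simulations. Each class is a fixed polyline skeleton in the
# unit square; rendering applies translation, slant (shear), scale and stroke
# thickness jitter, then rasterizes with an anti-aliased distance field.

GLYPH_DIM <- c(28L, 28L, 1L)

# Polyline skeletons per digit, in (x, y) with y increasing downwards.
# Each element is a list of strokes; a stroke is a 2-column matrix of points.
glyph_skeletons <- local({
  circle <- function(cx, cy, rx, ry, from = 0, to = 2 * pi, n = 24) {
    t <- seq(from, to, length.out = n)
    cbind(cx + rx * sin(t), cy - ry * cos(t))
  }
  list(
    `0` = list(circle(0.5, 0.5, 0.28, 0.4)),
    `1` = list(rbind(c(0.35, 0.25), c(0.55, 0.1), c(0.55, 0.9))),
    `2` = list(rbind(c(0.25, 0.3), c(0.35, 0.12), c(0.62, 0.12),
                     c(0.72, 0.3), c(0.3, 0.9), c(0.75, 0.9))),
    `3` = list(circle(0.5, 0.3, 0.22, 0.2, from = -pi / 2, to = pi * 0.9),
               circle(0.5, 0.7, 0.24, 0.22, from = -pi * 0.9, to = pi / 2)),
    `4` = list(rbind(c(0.6, 0.9), c(0.6, 0.1), c(0.2, 0.62), c(0.8, 0.62))),
    `5` = list(rbind(c(0.72, 0.1), c(0.3, 0.1), c(0.28, 0.45)),
               circle(0.48, 0.65, 0.25, 0.24, from = -pi * 0.85, to = pi * 0.6)),
    `6` = list(rbind(c(0.62, 0.1), c(0.34, 0.45), c(0.3, 0.65)),
               circle(0.5, 0.68, 0.2, 0.2)),
    `7` = list(rbind(c(0.25, 0.12), c(0.75, 0.12), c(0.42, 0.9))),
    `8` = list(circle(0.5, 0.3, 0.2, 0.19), circle(0.5, 0.72, 0.24, 0.22)),
    `9` = list(circle(0.5, 0.32, 0.2, 0.2),
               rbind(c(0.7, 0.32), c(0.66, 0.9)))
  )
})

# Minimum distance from each grid point to a segment (p, q).
seg_dist <- function(px, py, qx, qy, gx, gy) {
  vx <- qx - px; vy <- qy - py
  len2 <- vx^2 + vy^2
  if (len2 < 1e-12) return(sqrt((gx - px)^2 + (gy - py)^2))
  t <- ((gx - px) * vx + (gy - py) * vy) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  sqrt((gx - (px + t * vx))^2 + (gy - (py + t * vy))^2)
}

#' Render a digit-like glyph
#'
#' @param digit_class Integer 0-9.
#' @param style Optional list overriding jitter parameters: `dx`, `dy`
#'   (translation, px), `slant` (shear fraction), `scale` (relative), and
#'   `thickness` (stroke radius, px). Unset entries are drawn at random.
#' @param seed Optional integer seed.
#' @return A 28 x 28 x 1 array in `[0, 1]`.
#' @export
render_glyph <- function(digit_class, style = list(), seed = NULL) {
  if (!is.numeric(digit_class) || length(digit_class) != 1L ||
      !(digit_class %in% 0:9)) {
    stop("`digit_class` must be an integer in 0..9")
  }
  use_seed(seed)
  jit <- list(
    dx = stats::runif(1, -2, 2), dy = stats::runif(1, -2, 2),
    slant = stats::runif(1, -0.18, 0.18),
    scale = stats::runif(1, 0.85, 1.1),
    thickness = stats::runif(1, 0.8, 1.6)
  )
  jit[names(style)] <- style
  strokes <- glyph_skeletons[[as.character(digit_class)]]
  size <- 28
  gx <- matrix(rep(seq_len(size) - 0.5, each = size), size)   # column coord
  gy <- matrix(rep(seq_len(size) - 0.5, times = size), size)  # row coord
  img <- matrix(0, size, size)
  for (st in strokes) {
    x <- st[, 1]; y <- st[, 2]
    x <- x + jit$slant * (0.5 - y)                 # shear about mid-height
    x <- (x - 0.5) * jit$scale + 0.5
    y <- (y - 0.5) * jit$scale + 0.5
    px <- x * 20 + 4 + jit$dx
    py <- y * 20 + 4 + jit$dy
    for (i in seq_len(length(px) - 1L)) {
      d <- seg_dist(px[i], py[i], px[i + 1L], py[i + 1L], gx, gy)
      ink <- clip01(1 - (d - jit$thickness))       # 1 px anti-alias band
      img <- pmax(img, ink)
    }
  }
  array(img, GLYPH_DIM)
}

#' Render a batch of glyphs as a flat matrix
#'
#' @param classes Integer vector of digit classes.
#' @param seed Optional integer seed.
#' @return A `length(classes)` x 784 matrix of flattened glyphs.
#' @export
render_glyphs <- function(classes, seed = NULL) {
  use_seed(seed)
  t(vapply(classes, function(k) flatten_image(render_glyph(k)),
           numeric(prod(GLYPH_DIM))))
}
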