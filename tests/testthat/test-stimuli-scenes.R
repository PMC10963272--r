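test_that("factor sampling is seeded, in range, and shape-uniform", {
  f1 <- sample_factors(seed = 11)
  f2 <- sample_factors(seed = 11)
  expect_identical(f1, f2)

  fs <- sample_factors(10000, seed = 12, simplify = FALSE)
  hues <- unlist(lapply(fs, function(f) c(f$floor_hue, f$wall_hue,
                                          f$object_hue)))
  expect_true(all(hues >= 0 & hues < 1))
  # each shape frequency within 3 sigma of 0.25 under a binomial
  counts <- table(factor(vapply(fs, `[[`, "", "shape"),
                         levels = c("cube", "cylinder", "sphere", "capsule")))
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) < 3 * sigma))
})

test_that("scene rendering is deterministic with monotone object size", {
  f <- sample_factors(seed = 21)
  expect_identical(render_scene(f), render_scene(f))

  f1 <- f; f1$scale <- 0.3
  f2 <- f; f2$scale <- 0.8
  expect_gt(sum(scene_object_mask(f2)), sum(scene_object_mask(f1)))

  # top-left pixel takes the wall colour exactly
  f$floor_hue <- 0.1; f$wall_hue <- 0.5; f$object_hue <- 0.8
  img <- render_scene(f)
  wall <- 0.5 + 0.4 * cos(2 * pi * (0.5 + c(0, 1 / 3, 2 / 3)))
  expect_equal(img[1, 1, ], wall)
})

test_that("rendered scenes have hue-invariant sums and norms", {
  fs <- sample_factors(20, seed = 22, simplify = FALSE)
  X <- t(vapply(fs, function(f) flatten_image(render_scene(f)),
                numeric(64 * 64 * 3)))
  expect_true(all(X > 0 & X < 1))
  expect_lt(diff(range(rowSums(X))), 1e-8)
  expect_lt(diff(range(rowSums(X^2))), 1e-8)
})

test_that("novel-feature overlays blend towards white and validate bounds", {
  f <- sample_factors(seed = 31)
  img <- render_scene(f)
  expect_identical(add_novel_features(img, novelty_overlay()), img)

  sq <- function(op) novelty_overlay(data.frame(row = 10, col = 12, side = 5,
                                                opacity = op))
  out <- add_novel_features(img, sq(1))
  expect_equal(out[10:14, 12:16, ], array(1, c(5, 5, 3)))

  base <- img; base[10:14, 12:16, ] <- 0.2
  out <- add_novel_features(base, sq(0.5))
  expect_equal(out[10, 12, 1], 0.6)

  oob <- novelty_overlay(data.frame(row = 62, col = 1, side = 5,
                                    opacity = 0.5))
  expect_error(add_novel_features(img, oob), "bounds")
})

test_that("partial corruption zeroes exactly the requested count", {
  img <- render_scene(sample_factors(seed = 41))
  expect_identical(corrupt_partial(img, 0), img)
  expect_true(all(corrupt_partial(img, 1) == 0))
  out <- corrupt_partial(img, 0.1, seed = 42)
  expect_equal(sum(out == 0), floor(0.1 * 64 * 64 * 3))  # 1228
  expect_error(corrupt_partial(img, 1.2), "fraction")
})

test_that("zoom margins follow round(32/ratio - 32) and zooming crops or pads", {
  expect_identical(zoom_margin(1.0), 0L)
  expect_identical(zoom_margin(0.8), 8L)
  expect_identical(zoom_margin(1.2), -5L)

  f <- sample_factors(seed = 51)
  img <- render_scene(f)
  expect_identical(zoom_view(img, 1.0), img)
  expect_error(zoom_view(img, -1), "positive")

  # zooming in increases the fraction of object pixels (object-mask oracle)
  obj <- 0.5 + 0.4 * cos(2 * pi * (f$object_hue + c(0, 1 / 3, 2 / 3)))
  obj_frac <- function(x) {
    mean(abs(x[, , 1] - obj[1]) < 0.02 & abs(x[, , 2] - obj[2]) < 0.02 &
           abs(x[, , 3] - obj[3]) < 0.02)
  }
  expect_gt(obj_frac(zoom_view(img, 1.2)), obj_frac(img))
})

test_that("zoom out then in approximately restores the central region", {
  img <- render_scene(sample_factors(seed = 61))
  back <- zoom_view(zoom_view(img, 0.8), 1 / 0.8)
  centre <- 17:48
  expect_lt(mean(abs(back[centre, centre, ] - img[centre, centre, ])), 0.05)
})

test_that("sampled scenes are well separated relative to retrieval tolerance", {
  fs <- sample_factors(100, seed = 71, simplify = FALSE)
  X <- t(vapply(fs, function(f) flatten_image(render_scene(f)),
                numeric(64 * 64 * 3)))
  d <- as.matrix(stats::dist(X, method = "manhattan")) / ncol(X)
  diag(d) <- Inf
  expect_gt(min(d), 10 * 1e-4)
})
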