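# Distortion experiment batteries: prototypicality (intra-class variance
# before vs after recall), boundary extension/contraction (object-size change
# under artificial zoom), and context-driven distortion of an ambiguous
# stimulus encoded with an external concept.

#' Intra-class variance before and after recall
#'
#' Recalls every image through the generative network and compares per-pixel
#' variance within each class before and after recall; generative recall
#' pulls items towards class prototypes, shrinking the variance. The paired
#' t-test and Cohen's d are computed over all (pixel, class) variance pairs.
#'
#' @param vae A trained `vae`.
#' @param images Matrix of flattened images (rows) or list of arrays.
#' @param labels Class label per image.
#' @param min_per_class Classes with fewer images are excluded with a warning.
#' @return An object of class `prototypicality_report`: `variance_before`,
#'   `variance_after` (lists of per-pixel variance vectors per class),
#'   `t_statistic`, `df`, `p_value`, `cohens_d`, `mean_difference`,
#'   `conf_int`, `classes`.
#' @export
prototypicality_analysis <- function(vae, images, labels, min_per_class = 2L) {
  X <- as_input_matrix(vae, images)
  labels <- factor(labels)
  keep_classes <- names(which(table(labels) >= min_per_class))
  dropped <- setdiff(levels(labels), keep_classes)
  if (length(dropped) > 0) {
    warning(sprintf("excluding classes with < %d images: %s", min_per_class,
                    paste(dropped, collapse = ", ")))
  }
  R <- recall_basic(vae, X)
  var_before <- list(); var_after <- list()
  for (cl in keep_classes) {
    idx <- which(labels == cl)
    var_before[[cl]] <- apply(X[idx, , drop = FALSE], 2L, stats::var)
    var_after[[cl]] <- apply(R[idx, , drop = FALSE], 2L, stats::var)
  }
  before <- unlist(var_before); after <- unlist(var_after)
  diffs <- before - after
  tt <- stats::t.test(before, after, paired = TRUE)
  d <- mean(diffs) / stats::sd(diffs)
  structure(list(variance_before = var_before, variance_after = var_after,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 cohens_d = d, mean_difference = mean(diffs),
                 conf_int = unname(tt$conf.int), classes = keep_classes),
            class = "prototypicality_report")
}

#' @export
print.prototypicality_report <- function(x, ...) {
  cat(sprintf(paste0("prototypicality: mean per-pixel variance %.5f -> %.5f",
                     " after recall\n  paired t(%d) = %.2f, p = %.3g,",
                     " Cohen's d = %.3f\n"),
              mean(unlist(x$variance_before)), mean(unlist(x$variance_after)),
              x$df, x$t_statistic, x$p_value, x$cohens_d))
  invisible(x)
}

#' Estimate the central object's size on the image midline
#'
#' Quantizes the image to `k` colours by k-means, takes the dominant
#' quantized colour of the central window as the object colour, and returns
#' the fraction of pixels on the vertical midline assigned that colour.
#' Returns `NA` if the object colour is not distinct from the wall (top-left)
#' or floor (bottom-left) colour.
#'
#' @param image A scene image (H x W x 3).
#' @param k Number of colour clusters (4: floor, wall, object, other).
#' @param seed Seed for the k-means initialization.
#' @return Fraction in `[0, 1]`, or `NA` if the estimate is invalid.
#' @export
estimate_object_size <- function(image, k = 4L, seed = 0L) {
  stopifnot(k >= 2L, length(dim(image)) == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
              as.vector(image[, , 3]))
  use_seed(seed)
  n_distinct <- nrow(unique(px))
  k <- min(k, n_distinct)
  if (k < 2L) return(NA_real_)
  km <- suppressWarnings(stats::kmeans(px, centers = k, nstart = 5L,
                                       iter.max = 100L))
  assign_mat <- matrix(km$cluster, h, w)
  mid_r <- (h %/% 2 - 7L):(h %/% 2 + 8L)
  mid_c <- (w %/% 2 - 7L):(w %/% 2 + 8L)
  centre <- assign_mat[mid_r, mid_c]
  obj_cluster <- as.integer(names(which.max(table(centre))))
  wall_cluster <- assign_mat[2L, 2L]
  floor_cluster <- assign_mat[h - 1L, 2L]
  if (obj_cluster == wall_cluster || obj_cluster == floor_cluster) {
    return(NA_real_)
  }
  midline <- assign_mat[, w %/% 2]
  mean(midline == obj_cluster)
}

#' Scene filter for the boundary experiment
#'
#' Keeps cube scenes whose object hue is separated from both the wall and
#' floor hues (circular hue distance > `min_sep`), so the size estimator can
#' isolate the object colour.
#'
#' @param factors A [scene_factors()] object.
#' @param min_sep Minimum circular hue separation.
#' @return TRUE if the scene is usable.
#' @export
boundary_scene_ok <- function(factors, min_sep = 0.12) {
  hue_dist <- function(a, b) {d <- abs(a - b); min(d, 1 - d)}
  factors$shape == "cube" &&
    hue_dist(factors$object_hue, factors$wall_hue) > min_sep &&
    hue_dist(factors$object_hue, factors$floor_hue) > min_sep &&
    factors$scale >= 0.5 && factors$scale <= 0.9
}

#' Sample scenes that pass the boundary filter
#'
#' @param n Number of scenes required.
#' @param seed Optional integer seed.
#' @return A list of [scene_factors()] objects.
#' @export
sample_boundary_scenes <- function(n, seed = NULL) {
  use_seed(seed)
  out <- list()
  while (length(out) < n) {
    f <- sample_factors(1L)
    if (boundary_scene_ok(f)) out[[length(out) + 1L]] <- f
  }
  out
}

#' Boundary extension / contraction experiment
#'
#' For each scene and zoom ratio: zoom the image, corrupt it (the noisy cue),
#' recall it through the generative network, and estimate the central
#' object's midline size on the clean zoomed input and on the recall (the
#' cue's zeroed pixels would deflate the input estimate by the corruption
#' fraction, biasing every ratio upwards). The
#' per-trial size ratio (output / input) measures boundary distortion:
#' ratios > 1 at zoom < 1 indicate the recalled object is enlarged back
#' towards the typical view (boundary contraction of the scene), and
#' ratios < 1 at zoom > 1 the opposite (boundary extension).
#'
#' @param vae A trained scene `vae`.
#' @param scene_factors List of filtered [scene_factors()] (held out from
#'   training; see [sample_boundary_scenes()]).
#' @param ratios Zoom ratios to test.
#' @param corrupt_fraction Cue corruption fraction.
#' @param k Colour clusters for the size estimator.
#' @param seed Optional integer seed.
#' @return An object of class `boundary_report`: `trials` (data frame with
#'   `ratio`, `size_in`, `size_out`, `size_ratio`), `summary` (median size
#'   ratio and n per zoom level), `n_skipped`.
#' @export
boundary_experiment <- function(vae, scene_factors,
                                ratios = c(0.8, 0.9, 1.0, 1.1, 1.2),
                                corrupt_fraction = 0.1, k = 4L, seed = NULL) {
  use_seed(seed)
  trials <- list()
  n_skipped <- 0L
  for (f in scene_factors) {
    img <- render_scene(f)
    for (r in ratios) {
      zoomed <- zoom_view(img, r)
      noisy <- corrupt_partial(zoomed, corrupt_fraction)
      out <- recall_basic(vae, noisy)
      s_in <- estimate_object_size(zoomed, k = k)
      s_out <- estimate_object_size(out, k = k)
      if (is.na(s_in) || is.na(s_out) || s_in == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      trials[[length(trials) + 1L]] <-
        data.frame(ratio = r, size_in = s_in, size_out = s_out,
                   size_ratio = s_out / s_in)
    }
  }
  trials <- do.call(rbind, trials)
  summary <- do.call(rbind, lapply(split(trials, trials$ratio), function(d) {
    data.frame(ratio = d$ratio[1], median_size_ratio = stats::median(d$size_ratio),
               n = nrow(d))
  }))
  rownames(summary) <- NULL
  structure(list(trials = trials, summary = summary, n_skipped = n_skipped),
            class = "boundary_report")
}

#' @export
print.boundary_report <- function(x, ...) {
  cat("boundary extension / contraction (median object-size ratio per zoom):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Class prototype latents
#'
#' Mean posterior-mean latent over freshly rendered scenes of one shape
#' class; the conceptual representation of that class.
#'
#' @param vae A trained scene `vae`.
#' @param shape Shape class name.
#' @param n Number of scenes to average.
#' @param seed Optional integer seed.
#' @return A latent vector of length `latent_dim`.
#' @export
class_prototype_latents <- function(vae, shape, n = 50L, seed = NULL) {
  use_seed(seed)
  factors <- sample_factors(n, simplify = FALSE)
  factors <- lapply(factors, function(f) {f$shape <- shape; f})
  X <- t(vapply(factors, function(f) flatten_image(render_scene(f)),
                numeric(prod(SCENE_DIM))))
  colMeans(forward_encoder(vae, X)$mu)
}

#' Render an ambiguous stimulus between two shape classes
#'
#' Pixel-space average of the scene rendered with each of two shapes (other
#' factors shared), Gaussian-blurred; the ambiguous figure used in
#' context-at-encoding distortion experiments.
#'
#' @param base_factors A [scene_factors()] object (its shape is ignored).
#' @param shapes Two shape names to blend.
#' @param blur_sigma Gaussian blur radius in pixels.
#' @return A 64 x 64 x 3 image.
#' @export
ambiguous_stimulus <- function(base_factors, shapes = c("cube", "sphere"),
                               blur_sigma = 2) {
  stopifnot(length(shapes) == 2L)
  f1 <- base_factors; f1$shape <- shapes[1]
  f2 <- base_factors; f2$shape <- shapes[2]
  img <- (render_scene(f1) + render_scene(f2)) / 2
  clip01(EBImage::gblur(img, sigma = blur_sigma))
}

#' Context-at-encoding distortion experiment
#'
#' Encodes the same ambiguous stimulus (plus a novel overlay square) twice,
#' once with each class's prototype latents as the conceptual context, and
#' recalls each from a noisy cue. Recall is distorted towards the encoded
#' context: the recalled image is closer to the cued class's decoded
#' prototype than to the alternative's. The encoding threshold defaults to
#' 0.3, high enough that the scene structure the context predicts is carried
#' by the conceptual slot and only genuinely novel features (the overlay
#' square, the ambiguous object's core) are stored veridically; at low
#' thresholds nearly every pixel is stored and recall no longer depends on
#' the context.
#'
#' @param vae A trained scene `vae`.
#' @param base_factors Base [scene_factors()] for the ambiguous stimulus.
#' @param shapes Two class names providing the contexts.
#' @param threshold Encoding error threshold.
#' @param corrupt_fraction Cue corruption fraction.
#' @param latent_scale Conceptual-slot scale (see [estimate_latent_scale()]).
#' @param seed Optional integer seed.
#' @return A list per context class: `recall` (final image), `prototype`
#'   (decoded context), `dist_to_cued`, `dist_to_other` (mean absolute
#'   distances of the recall to each class prototype image).
#' @export
carmichael_experiment <- function(vae, base_factors,
                                  shapes = c("cube", "sphere"),
                                  threshold = 0.3, corrupt_fraction = 0.1,
                                  latent_scale = 1, seed = NULL) {
  use_seed(seed)
  stim <- ambiguous_stimulus(base_factors, shapes)
  stim <- add_novel_features(stim, sample_overlay(n_squares = 1L,
                                                  opacity_range = c(1, 1)))
  protos <- lapply(shapes, function(s) {
    z <- class_prototype_latents(vae, s, seed = sample.int(2^31 - 1, 1L))
    list(z = z, image = vae_decode(vae, z))
  })
  names(protos) <- shapes
  cue <- corrupt_partial(stim, corrupt_fraction)
  out <- lapply(shapes, function(s) {
    store <- extended_store(vae, latent_scale = latent_scale)
    store <- encode_event_with_context(store, vae, stim, protos[[s]]$z,
                                       threshold)
    rec <- recall_extended(store, vae, cue, threshold)
    other <- setdiff(shapes, s)
    list(recall = rec$image, prototype = protos[[s]]$image,
         dist_to_cued = mean(abs(rec$image - protos[[s]]$image)),
         dist_to_other = mean(abs(rec$image - protos[[other]]$image)))
  })
  names(out) <- shapes
  out
}
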