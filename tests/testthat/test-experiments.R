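test_that("the midline size estimator recovers the rendered object size", {
  f <- scene_factors(floor_hue = 0.05, wall_hue = 0.45, object_hue = 0.75,
                     shape = "cube", scale = 0.6)
  img <- render_scene(f)
  truth <- mean(scene_object_mask(f)[, 32])
  est <- estimate_object_size(img, k = 4L)
  expect_false(is.na(est))
  expect_lt(abs(est - truth), 2 / 64)  # within two pixels on the midline
  # deterministic across repeated seeded runs
  expect_identical(est, estimate_object_size(img, k = 4L))

  tiny <- scene_factors(0.05, 0.45, 0.75, "cube", scale = 0.01)
  est_tiny <- estimate_object_size(render_scene(tiny), k = 4L)
  expect_true(is.na(est_tiny) || est_tiny < 0.12)
})

test_that("prototypicality: generative recall shrinks intra-class variance", {
  g <- glyph_run()
  idx <- seq_len(1000)
  rep <- prototypicality_analysis(g$vae, g$x[idx, ], g$classes[idx])
  expect_length(rep$variance_before, 10L)
  expect_equal(rep$df, length(unlist(rep$variance_before)) - 1)

  # per-class mean variance falls for at least 9 of 10 classes
  drop_per_class <- vapply(names(rep$variance_before), function(cl) {
    mean(rep$variance_before[[cl]]) > mean(rep$variance_after[[cl]])
  }, logical(1))
  expect_gte(sum(drop_per_class), 9L)
  expect_gt(rep$t_statistic, 0)
  expect_gt(rep$cohens_d, 0)

  # degenerate case: variance of identical images is zero
  two <- rbind(g$x[1, ], g$x[1, ])
  rep2 <- suppressWarnings(prototypicality_analysis(g$vae, rbind(two, g$x[2:3, ]),
                                                    c("a", "a", "b", "b")))
  expect_equal(sum(rep2$variance_before[["a"]]), 0)
})

test_that("excluding undersized classes warns", {
  g <- glyph_run()
  expect_warning(prototypicality_analysis(g$vae, g$x[1:3, ], c("a", "a", "b")),
                 "excluding")
})

test_that("zoomed views are recalled towards the typical object size", {
  sys <- std_run()
  scenes <- sample_boundary_scenes(60, seed = 1)
  rep <- boundary_experiment(sys$run$vae, scenes, seed = 2)
  s <- rep$summary[order(rep$summary$ratio), ]
  expect_gt(s$median_size_ratio[s$ratio == 0.8], 1)
  expect_lt(s$median_size_ratio[s$ratio == 1.2], 1)
  expect_lt(abs(s$median_size_ratio[s$ratio == 1.0] - 1), 0.25)
  # monotone decreasing across the zoom grid
  expect_true(all(diff(s$median_size_ratio) < 0))
})

test_that("ambiguous stimuli are recalled towards their encoded concept", {
  sys <- std_run()
  vae <- sys$run$vae
  scale <- estimate_latent_scale(
    vae, lapply(sample_factors(50, seed = 3, simplify = FALSE), render_scene))
  res <- carmichael_experiment(vae, sample_factors(seed = 4),
                               latent_scale = scale, seed = 5)
  expect_lt(res$cube$dist_to_cued, res$cube$dist_to_other)
  expect_lt(res$sphere$dist_to_cued, res$sphere$dist_to_other)
})
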