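test_that("decomposition splits events by per-pixel prediction error", {
  s <- small_scene_vae()
  img <- add_novel_features(render_scene(sample_factors(seed = 1)),
                            sample_overlay(seed = 2))
  tr_inf <- decompose_event(s$vae, img, Inf)
  expect_true(all(tr_inf$sensory == 0))
  expect_equal(tr_inf$conceptual, vae_encode(s$vae, img)$mu)

  tr0 <- decompose_event(s$vae, img, 0)
  expect_true(all((tr0$error_map > 0) == tr0$mask))
  # support is monotone non-increasing in the threshold (set inclusion)
  ths <- c(0, 0.05, 0.1, 0.2, 0.4)
  masks <- lapply(ths, function(t) decompose_event(s$vae, img, t)$mask)
  for (i in seq_len(length(ths) - 1L)) {
    expect_true(all(masks[[i]] | !masks[[i + 1]]))  # mask[i+1] subset mask[i]
  }
})

test_that("novel overlay squares are flagged unpredictable at moderate thresholds", {
  s <- small_scene_vae()
  base <- render_scene(sample_factors(seed = 3))
  ov <- novelty_overlay(data.frame(row = 8, col = 8, side = 6, opacity = 1))
  img <- add_novel_features(base, ov)
  tr <- decompose_event(s$vae, img, 0.15)
  expect_gt(mean(tr$mask[8:13, 8:13]), 0.9)
})

test_that("encoding and recall round-trip through the combined trace", {
  s <- small_scene_vae()
  imgs <- lapply(1:20, function(i) {
    add_novel_features(render_scene(sample_factors(seed = 10 + i)),
                       sample_overlay(seed = 40 + i))
  })
  scale <- estimate_latent_scale(s$vae, imgs)
  store <- extended_store(s$vae, latent_scale = scale)
  for (im in imgs) store <- encode_event(store, s$vae, im, 0.1)
  expect_identical(nrow(store$patterns), 20L)

  # full-image cue retrieves the event's own trace; nearest-trace property
  # checked against brute-force distance over combined vectors
  rec <- recall_extended(store, s$vae, imgs[[7]], 0.1)
  q <- genmem:::trace_vector(store, decompose_event(s$vae, imgs[[7]], 0.1)$sensory,
                    decompose_event(s$vae, imgs[[7]], 0.1)$conceptual)
  nn <- which.min(colSums((t(store$patterns) - q)^2))
  expect_identical(nn, 7L)
  expect_true(rec$converged)
  expect_equal(which.max(rec$weights), 7L)
})

test_that("threshold zero guarantees perfect recall of the encoded event", {
  s <- small_scene_vae()
  img <- add_novel_features(render_scene(sample_factors(seed = 30)),
                            sample_overlay(seed = 31))
  store <- extended_store(s$vae,
                          latent_scale = estimate_latent_scale(s$vae,
                                                               list(img)))
  store <- encode_event(store, s$vae, img, 0)
  cue <- corrupt_partial(img, 0.1, seed = 32)
  rec <- recall_extended(store, s$vae, cue, 0)
  expect_equal(max(abs(rec$image - img)), 0, tolerance = 1e-12)
})

test_that("recall error grows with the encoding threshold for a single event", {
  s <- small_scene_vae()
  img <- add_novel_features(render_scene(sample_factors(seed = 40)),
                            sample_overlay(seed = 41))
  cue <- corrupt_partial(img, 0.1, seed = 42)
  errs <- vapply(c(0, 0.05, 0.1, 0.2, 0.4), function(th) {
    store <- extended_store(s$vae, latent_scale = 1)
    store <- encode_event(store, s$vae, img, th)
    mean(abs(recall_extended(store, s$vae, cue, th)$image - img))
  }, numeric(1))
  expect_true(all(diff(errs) >= 0))
})

test_that("context at encoding replaces the conceptual slot and stores its residuals", {
  s <- small_scene_vae()
  img <- render_scene(sample_factors(seed = 50))
  own <- vae_encode(s$vae, img)$mu
  st1 <- encode_event(extended_store(s$vae), s$vae, img, 0.1)
  st2 <- encode_event_with_context(extended_store(s$vae), s$vae, img, own,
                                   0.1)
  expect_equal(st1$patterns, st2$patterns)

  # an overlay square is unpredicted by any class prototype
  ov_img <- add_novel_features(img, novelty_overlay(
    data.frame(row = 5, col = 5, side = 6, opacity = 1)))
  proto_z <- class_prototype_latents(s$vae, "cube", n = 20, seed = 51)
  st3 <- encode_event_with_context(extended_store(s$vae), s$vae, ov_img,
                                   proto_z, 0.15)
  tr <- attr(st3, "last_trace")
  expect_gt(mean(tr$mask[5:10, 5:10]), 0.9)
  expect_equal(tr$conceptual, proto_z)
})

test_that("extended replay returns attractor traces that split cleanly", {
  s <- small_scene_vae()
  store <- extended_store(s$vae, latent_scale = 1)
  for (i in 1:10) {
    store <- encode_event(store, s$vae,
                          render_scene(sample_factors(seed = 60 + i)), 0.1)
  }
  reps <- replay_extended(store, n = 20, seed = 61)
  for (r in reps) {
    d <- min(rowMeans(abs(store$patterns -
                            matrix(r$combined, nrow(store$patterns),
                                   ncol(store$patterns), byrow = TRUE))))
    expect_lt(d, 1e-4)
    expect_identical(dim(r$sensory), c(64L, 64L, 3L))
    expect_length(r$conceptual, 20L)
    dec <- vae_decode(s$vae, r$conceptual)
    expect_true(all(dec >= 0 & dec <= 1))
  }
})

test_that("the threshold sweep validates its grid", {
  s <- small_scene_vae()
  img <- list(render_scene(sample_factors(seed = 70)))
  expect_error(threshold_sweep(s$vae, img, thresholds = c(0.2, 0.1)),
               "increasing")
  # thresholds above the maximum error store nothing
  sw <- suppressWarnings(threshold_sweep(s$vae, img, thresholds = c(2, 3, 4),
                                         seed = 71))
  expect_true(all(sw$rows$mean_stored_pixels == 0))
})
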