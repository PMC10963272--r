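test_that("the readout separates separable latents and rejects degenerate input", {
  set.seed(1)
  lat <- rbind(matrix(rnorm(100, mean = 3), 50, 2),
               matrix(rnorm(100, mean = -3), 50, 2))
  lab <- rep(c("a", "b"), each = 50)
  ro <- fit_readout(lat[c(1:40, 51:90), ], lab[c(1:40, 51:90)])
  expect_equal(mean(predict(ro, lat[c(41:50, 91:100), ]) ==
                      lab[c(41:50, 91:100)]), 1)
  expect_error(fit_readout(lat, rep("a", 100)), "two classes")
})

test_that("shuffled labels decode at chance", {
  set.seed(2)
  lat <- matrix(rnorm(400 * 5), 400)
  lab <- sample(rep(c("a", "b"), each = 200))
  ro <- fit_readout(lat[1:200, ], lab[1:200])
  acc <- mean(predict(ro, lat[201:400, ]) == lab[201:400])
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / 200))
})

test_that("spearman_rho matches hand-computed ranks and flags constants", {
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(1:3, 1:3), 1)
  expect_equal(spearman_rho(1:3, c(1, 3, 2)), 0.5)
  expect_warning(r <- spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_true(is.na(r))
})

test_that("a single-memory store consolidates onto that memory", {
  probes <- scene_probes(1, seed = 3)
  st <- hopfield_store(probes$x, beta = 20)
  cfg <- vae_config(c(64L, 64L, 3L), latent_dim = 4L, hidden = c(32L),
                    max_epochs = 6L, batch_size = 16L)
  run <- consolidate(st, cfg, n_replay = 64L, seed = 4)
  expect_identical(nrow(run$log), length(run$log$decoding_accuracy))
  err_own <- mean(abs(recall_basic(run$vae, probes$x[1, ]) - probes$x[1, ]))
  other <- flatten_image(render_scene(sample_factors(seed = 5)))
  err_other <- mean(abs(recall_basic(run$vae, other) - other))
  expect_lt(err_own, err_other)
})

test_that("semantic recall from latents is robust and decoder-free", {
  sys <- std_run()
  run <- sys$run
  probes <- scene_probes(100, seed = 6)
  acc <- mean(as.character(semantic_recall(run$vae, run$readout, probes$x)) ==
                as.character(probes$labels))
  expect_gt(acc, 0.33)  # 4-way task, chance 0.25

  # corrupted cues still decode above chance and near the clean accuracy
  corrupted <- t(vapply(seq_len(100), function(i) {
    flatten_image(corrupt_partial(unflatten_image(probes$x[i, ],
                                                  c(64L, 64L, 3L)),
                                  0.1, seed = 600 + i))
  }, numeric(ncol(probes$x))))
  acc_corrupted <- mean(as.character(
    semantic_recall(run$vae, run$readout, corrupted)) ==
      as.character(probes$labels))
  expect_gt(acc_corrupted, 0.3)
  expect_lt(acc - acc_corrupted, 0.15)

  # an untrained network decodes at chance
  cfg <- vae_config(c(64L, 64L, 3L), latent_dim = 20L, hidden = c(64L))
  v0 <- vae_new(cfg, seed = 7)
  mu0 <- vae_encode(v0, probes$x)$mu
  tr <- scene_probes(200, seed = 8)
  ro0 <- fit_readout(vae_encode(v0, tr$x)$mu, tr$labels)
  acc0 <- mean(as.character(predict(ro0, mu0)) == as.character(probes$labels))
  expect_lt(abs(acc0 - 0.25), 3 * sqrt(0.25 * 0.75 / 100) + 0.1)
})

test_that("consolidation on replay approaches training on the originals", {
  s <- small_scene_vae()
  st <- hopfield_store(s$probes$x, beta = 20)
  rep <- hopfield_replay(st, 300, seed = 9)
  fit_replay <- vae_train(vae_new(scene_vae_config(max_epochs = 8L),
                                  seed = 1L), rep$samples, seed = 2L)
  err_replay <- fit_replay$log$recon[nrow(fit_replay$log)]
  err_orig <- s$log$recon[nrow(s$log)]
  expect_gt(err_replay / err_orig, 0.9)
  expect_lt(err_replay / err_orig, 1.5)
})

test_that("latents support few-shot readout better than raw pixels", {
  sys <- std_run()
  tr <- scene_probes(200, seed = 10)
  te <- scene_probes(300, seed = 11)
  mu_tr <- vae_encode(sys$run$vae, tr$x)$mu
  mu_te <- vae_encode(sys$run$vae, te$x)$mu
  acc_lat <- mean(predict(fit_readout(mu_tr, tr$labels), mu_te) == te$labels)
  acc_pix <- mean(predict(fit_readout(tr$x, tr$labels), te$x) == te$labels)
  expect_gte(acc_lat, acc_pix)
})
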