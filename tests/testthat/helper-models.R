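# Shared heavyweight fixtures, built once per test run and memoized. The
# standard consolidation run mirrors the package's reference setup (2,000
# stored scenes, 2,000 replay samples, 50 epochs); smaller fixtures serve
# unit tests that only need a roughly trained model.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, .fixtures)) assign(name, build(), .fixtures)
  get(name, .fixtures)
}

# Full-scale consolidation run: scene MHN -> replay -> VAE with per-epoch
# semantic readout.
std_run <- function() {
  memo("std_run", function() {
    probes <- scene_probes(2000L, seed = 101L)
    store <- hopfield_store(probes$x, beta = 20)
    run <- consolidate(store, scene_vae_config(), n_replay = 2000L,
                       seed = 202L)
    list(probes = probes, store = store, run = run)
  })
}

# Small, quickly trained scene VAE for unit tests that just need a model
# whose reconstructions are meaningful.
small_scene_vae <- function() {
  memo("small_scene_vae", function() {
    probes <- scene_probes(300L, seed = 303L)
    fit <- vae_train(vae_new(scene_vae_config(max_epochs = 8L), seed = 1L),
                     probes$x, seed = 2L)
    list(vae = fit$vae, probes = probes, log = fit$log)
  })
}

# Glyph pipeline: glyph MHN -> replay -> VAE (for prototypicality).
glyph_run <- function() {
  memo("glyph_run", function() {
    classes <- rep(0:9, each = 100L)
    x <- render_glyphs(classes, seed = 404L)
    store <- hopfield_store(x, beta = 20)
    rep <- hopfield_replay(store, 1000L, seed = 405L)
    cfg <- vae_config(c(28L, 28L, 1L), latent_dim = 20L, hidden = c(256L),
                      max_epochs = 30L)
    fit <- vae_train(vae_new(cfg, seed = 3L), rep$samples, seed = 4L)
    list(vae = fit$vae, x = x, classes = classes)
  })
}

# DRM pipeline: synthetic corpus -> filtered -> bag-of-words VAE.
drm_fit <- function() {
  memo("drm_fit", function() {
    corpus <- preprocess_corpus(generate_corpus(seed = 505L))
    fit <- train_bow_vae(corpus, seed = 506L)
    list(corpus = corpus, vae = fit$vae, log = fit$log)
  })
}

# Threshold sweep on the standard run (100 overlay events, 5 thresholds);
# shared by the sweep and threshold-zero tests.
std_sweep <- function() {
  memo("std_sweep", function() {
    sys <- std_run()
    set.seed(607L)
    events <- lapply(sample_factors(100L, simplify = FALSE), function(f) {
      add_novel_features(render_scene(f), sample_overlay())
    })
    threshold_sweep(sys$run$vae, events, seed = 608L)
  })
}
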