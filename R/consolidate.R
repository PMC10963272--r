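# Teacher-student consolidation: the Hopfield store (hippocampal teacher)
# replays stored events from random-noise queries and the VAE (neocortical
# student) is trained on the replayed set. A max-margin linear readout fitted
# on latent means tracks the emergence of semantic structure (decoding
# accuracy) at the end of every epoch.

#' Fit a semantic readout on latent vectors
#'
#' A support vector machine with a linear kernel (cost 1, no rescaling),
#' deterministic given the data.
#'
#' @param latents Numeric matrix (rows are latent vectors).
#' @param labels Factor or vector of class labels (>= 2 classes present).
#' @param cost SVM cost parameter.
#' @return An object of class `readout` (predict method available).
#' @export
fit_readout <- function(latents, labels, cost = 1) {
  latents <- as.matrix(latents)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("at least two classes are required to fit a readout")
  }
  fit <- e1071::svm(x = latents, y = droplevels(labels), kernel = "linear",
                    cost = cost, scale = FALSE)
  structure(list(svm = fit, categories = levels(droplevels(labels))),
            class = "readout")
}

#' @export
predict.readout <- function(object, newdata, ...) {
  stats::predict(object$svm, as.matrix(newdata))
}

#' Semantic recall from a partial input
#'
#' Classifies the latent posterior mean of the input; no decoder pass is
#' needed, so semantic retrieval survives a decoder lesion.
#'
#' @param vae A trained `vae`.
#' @param readout A [fit_readout()] classifier.
#' @param partial Input image (or matrix of flattened rows).
#' @return Predicted label(s).
#' @export
semantic_recall <- function(vae, readout, partial) {
  mu <- forward_encoder(vae, as_input_matrix(vae, partial))$mu
  predict(readout, mu)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Returns `NA` with a warning
#' if either input is constant (the statistic is undefined).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A value in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("spearman_rho is undefined for constant input")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Reference VAE configuration for scene stimuli
#'
#' The package's standard image model: a shared 4x4 patch embedding (32
#' features per patch) feeding a 256-unit dense core, 20 latents, MAE
#' reconstruction loss, trained with AMSGrad (learning rate 0.001, batches
#' of 64) for up to `max_epochs` epochs. Early stopping uses a long patience
#' (10 epochs, minimum improvement 1e-5) so that slow late-stage gains in
#' the latent space are not cut off.
#'
#' @param max_epochs Maximum training epochs.
#' @param ... Overrides passed to [vae_config()].
#' @return A [vae_config()].
#' @export
scene_vae_config <- function(max_epochs = 50L, ...) {
  vae_config(input_shape = SCENE_DIM, latent_dim = 20L, hidden = c(256L),
             arch = "patch", patch_size = 4L, patch_embed = 32L,
             max_epochs = max_epochs, patience = 10L, min_delta = 1e-5, ...)
}

#' Generate labelled scene probes
#'
#' Renders freshly sampled scenes with their shape labels; the labelled probe
#' set used to fit and evaluate the semantic readout.
#'
#' @param n Number of scenes.
#' @param seed Optional integer seed.
#' @return A list: `x` (n x 12288 matrix of flattened scenes), `labels`
#'   (factor of shape classes), `factors` (list of [scene_factors()]).
#' @export
scene_probes <- function(n, seed = NULL) {
  use_seed(seed)
  factors <- sample_factors(n, simplify = FALSE)
  x <- t(vapply(factors, function(f) flatten_image(render_scene(f)),
                numeric(prod(SCENE_DIM))))
  list(x = x, labels = factor(vapply(factors, `[[`, "", "shape"),
                              levels = SCENE_SHAPES),
       factors = factors)
}

#' Consolidate a Hopfield store into a generative network
#'
#' Draws `n_replay` replay samples once from the store, trains a fresh VAE on
#' them, and records held-out semantic decoding accuracy at the end of each
#' epoch: a readout is refitted from scratch on `n_probe_train` labelled
#' probe latents and evaluated on a fixed set of `n_probe_test` probes.
#'
#' @param store A [hopfield_store()].
#' @param vae_config A [vae_config()].
#' @param n_replay Number of replay samples used as the training set.
#' @param probe_fn `function(n, seed)` returning `list(x, labels)` of
#'   labelled evaluation stimuli (default [scene_probes()]).
#' @param seed Optional integer seed controlling replay, initialization,
#'   training and probes.
#' @param n_probe_train,n_probe_test Probe set sizes. The readout is fitted
#'   on 200 examples; the held-out set is 2,000 so that its binomial noise
#'   (s.d. ~0.01) stays small relative to the accuracy curve's rise at desk
#'   scale.
#' @return An object of class `consolidation_run`: `vae` (trained), `log`
#'   (per-epoch reconstruction error, KL and `decoding_accuracy`), `store`,
#'   `n_replay`, `readout` (from the final epoch).
#' @export
consolidate <- function(store, vae_config, n_replay, probe_fn = scene_probes,
                        seed = NULL, n_probe_train = 200L,
                        n_probe_test = 2000L) {
  stopifnot(inherits(store, "hopfield_store"), n_replay >= 1L)
  use_seed(seed)
  replay_seed <- sample.int(2^31 - 1, 1L)
  init_seed <- sample.int(2^31 - 1, 1L)
  train_seed <- sample.int(2^31 - 1, 1L)
  probe_seed <- sample.int(2^31 - 1, 1L)

  rep <- hopfield_replay(store, n_replay, seed = replay_seed)
  probes_train <- probe_fn(n_probe_train, seed = probe_seed)
  probes_test <- probe_fn(n_probe_test, seed = probe_seed + 1L)

  last_readout <- NULL
  eval_fn <- function(vae, epoch) {
    mu_train <- forward_encoder(vae, probes_train$x)$mu
    mu_test <- forward_encoder(vae, probes_test$x)$mu
    ro <- fit_readout(mu_train, probes_train$labels)
    acc <- mean(as.character(predict(ro, mu_test)) ==
                  as.character(probes_test$labels))
    last_readout <<- ro
    list(decoding_accuracy = acc)
  }

  vae <- vae_new(vae_config, seed = init_seed)
  fit <- vae_train(vae, rep$samples, seed = train_seed, eval_fn = eval_fn)
  structure(list(vae = fit$vae, log = fit$log, store = store,
                 n_replay = n_replay, readout = last_readout,
                 replay = rep$samples),
            class = "consolidation_run")
}

#' @export
print.consolidation_run <- function(x, ...) {
  cat(sprintf(paste0("consolidation run: %d replay samples, %d epochs, final",
                     " recon %.4f, final decoding accuracy %.3f\n"),
              x$n_replay, nrow(x$log), x$log$recon[nrow(x$log)],
              x$log$decoding_accuracy[nrow(x$log)]))
  invisible(x)
}
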