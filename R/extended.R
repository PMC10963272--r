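# Extended model: each event is split into a conceptual component (the
# generative network's latent variables) and an unpredicted sensory component
# (pixels whose reconstruction error exceeds a threshold, stored veridically;
# all other pixels zero). The two are concatenated into a single trace and
# stored in a modern Hopfield network. Recall decomposes the cue the same
# way, pattern-completes the combined vector, decodes the retrieved latents
# into a prototypical image, and overwrites it with the retrieved non-zero
# sensory features. Latents are divided by a fixed scale (the maximum
# absolute latent over a reference set) before concatenation so that neither
# slot dominates the softmax similarity.

#' Create an empty extended memory store
#'
#' @param vae The trained generative network whose latents define the
#'   conceptual slot.
#' @param latent_scale Positive scale by which latents are divided before
#'   storage (see [estimate_latent_scale()]).
#' @param beta Inverse temperature of the underlying Hopfield network.
#' @return An object of class `ext_store` with zero stored traces.
#' @export
extended_store <- function(vae, latent_scale = 1, beta = 20) {
  stopifnot(inherits(vae, "vae"), latent_scale > 0)
  D <- vae$config$input_dim
  L <- vae$config$latent_dim
  structure(list(patterns = matrix(numeric(0), 0L, D + L), D = D, L = L,
                 input_shape = vae$config$input_shape,
                 latent_scale = latent_scale, beta = beta),
            class = "ext_store")
}

#' @export
print.ext_store <- function(x, ...) {
  cat(sprintf("extended memory store: %d traces (%d sensory + %d conceptual units), beta = %g\n",
              nrow(x$patterns), x$D, x$L, x$beta))
  invisible(x)
}

#' Estimate the latent scale from a reference set
#'
#' The maximum absolute posterior-mean component over the reference inputs;
#' dividing latents by it puts the conceptual slot on the scale of pixel
#' values.
#'
#' @param vae A trained `vae`.
#' @param x Reference inputs (matrix of flattened rows or list of arrays).
#' @return A positive scalar.
#' @export
estimate_latent_scale <- function(vae, x) {
  mu <- forward_encoder(vae, as_input_matrix(vae, x))$mu
  s <- max(abs(mu))
  if (s <= 0) 1 else s
}

#' Decompose an event into conceptual and unpredicted sensory components
#'
#' The per-pixel prediction error is the mean absolute difference between the
#' input and the VAE's reconstruction, averaged over channels. Pixels with
#' error above `threshold` form the sensory component (all channel values
#' kept, zeros elsewhere); the posterior mean is the conceptual component.
#'
#' @param vae A trained `vae`.
#' @param image An input image array.
#' @param threshold Non-negative error threshold; `Inf` yields a purely
#'   conceptual trace, 0 stores every imperfectly predicted pixel.
#' @return An object of class `memory_trace`: `sensory` (image-shaped array,
#'   sparse), `conceptual` (latent vector), `mask` (H x W logical),
#'   `error_map` (H x W matrix), `threshold`.
#' @export
decompose_event <- function(vae, image, threshold) {
  stopifnot(threshold >= 0)
  recon <- recall_basic(vae, image)
  mu <- vae_encode(vae, image)$mu
  err <- abs(image - recon)
  error_map <- apply(err, c(1, 2), mean)
  mask <- error_map > threshold
  sensory <- image * array(rep(mask, dim(image)[3]), dim(image))
  structure(list(sensory = sensory, conceptual = mu, mask = mask,
                 error_map = error_map, threshold = threshold),
            class = "memory_trace")
}

# Combined storage row for a trace.
trace_vector <- function(store, sensory, conceptual) {
  c(flatten_image(sensory), conceptual / store$latent_scale)
}

split_combined <- function(store, v) {
  list(sensory = unflatten_image(v[seq_len(store$D)], store$input_shape),
       conceptual = v[store$D + seq_len(store$L)] * store$latent_scale)
}

#' Encode an event into the extended store
#'
#' Decomposes the image at the given threshold and appends the combined
#' trace. Returns the updated store (functional update).
#'
#' @param store An [extended_store()].
#' @param vae The generative network used for decomposition.
#' @param image Input image array.
#' @param threshold Encoding error threshold.
#' @return The updated `ext_store` with the new trace as attribute
#'   `"last_trace"`.
#' @export
encode_event <- function(store, vae, image, threshold) {
  stopifnot(inherits(store, "ext_store"))
  trace <- decompose_event(vae, image, threshold)
  store$patterns <- rbind(store$patterns,
                          trace_vector(store, trace$sensory, trace$conceptual))
  attr(store, "last_trace") <- trace
  store
}

#' Encode an event under an externally provided conceptual context
#'
#' Instead of the encoder's own latents, the supplied `context_latents`
#' occupy the conceptual slot, and the sensory component is computed relative
#' to the *context prototype* (the decoded context), storing whatever the
#' context fails to predict. Models encoding an ambiguous stimulus under an
#' externally suggested concept.
#'
#' @param store An [extended_store()].
#' @param vae The generative network.
#' @param image Input image array.
#' @param context_latents Length-L latent vector representing the context
#'   concept (e.g. a class prototype).
#' @param threshold Encoding error threshold.
#' @return The updated `ext_store`.
#' @export
encode_event_with_context <- function(store, vae, image, context_latents,
                                      threshold) {
  stopifnot(inherits(store, "ext_store"),
            length(context_latents) == store$L, threshold >= 0)
  prototype <- vae_decode(vae, context_latents)
  error_map <- apply(abs(image - prototype), c(1, 2), mean)
  mask <- error_map > threshold
  sensory <- image * array(rep(mask, dim(image)[3]), dim(image))
  store$patterns <- rbind(store$patterns,
                          trace_vector(store, sensory, context_latents))
  attr(store, "last_trace") <- structure(
    list(sensory = sensory, conceptual = context_latents, mask = mask,
         error_map = error_map, threshold = threshold),
    class = "memory_trace")
  store
}

# Retrieve combined vectors for a batch of queries against an ext_store.
ext_retrieve <- function(store, Q, max_steps = 10L, tol = 1e-4) {
  hs <- hopfield_store(store$patterns, beta = store$beta)
  hopfield_iterate(hs, Q, max_steps, tol)
}

#' Recall an event from a partial cue in the extended model
#'
#' Stages: (1) decompose the cue at `threshold`; (2) Hopfield pattern
#' completion on the combined vector; (3) decode the retrieved conceptual
#' latents into a prototypical image; (4) overwrite the prototype with the
#' retrieved non-zero sensory features.
#'
#' @param store A populated [extended_store()].
#' @param vae The generative network.
#' @param partial Partial/noisy cue image.
#' @param threshold Decomposition threshold (normally the encoding one).
#' @param nonzero_tol Magnitude below which a retrieved sensory entry is
#'   treated as "not stored".
#' @return A list: `image` (final recall), `prototype` (schema-based
#'   prediction), `sensory` (retrieved sensory features), `conceptual`
#'   (retrieved latents), `query` (the cue's `memory_trace`), `weights`,
#'   `converged`.
#' @export
recall_extended <- function(store, vae, partial, threshold,
                            nonzero_tol = 1e-8) {
  stopifnot(inherits(store, "ext_store"), nrow(store$patterns) >= 1L)
  qtrace <- decompose_event(vae, partial, threshold)
  q <- trace_vector(store, qtrace$sensory, qtrace$conceptual)
  r <- ext_retrieve(store, matrix(q, nrow = 1L))
  parts <- split_combined(store, drop(r$patterns))
  prototype <- vae_decode(vae, parts$conceptual)
  final <- prototype
  keep <- abs(parts$sensory) > nonzero_tol
  final[keep] <- parts$sensory[keep]
  list(image = final, prototype = prototype, sensory = parts$sensory,
       conceptual = parts$conceptual, query = qtrace,
       weights = drop(r$weights), converged = r$converged[1L])
}

#' Replay combined traces from random noise
#'
#' Noise queries are uniform over `[0, 1]` in the sensory slot and over the
#' scaled latent range in the conceptual slot; each retrieved combined vector
#' is split back into its components.
#'
#' @param store A populated [extended_store()].
#' @param n Number of replay samples.
#' @param seed Optional integer seed.
#' @return A list of `n` elements, each `list(sensory, conceptual, combined,
#'   converged)`.
#' @export
replay_extended <- function(store, n = 1L, seed = NULL) {
  stopifnot(inherits(store, "ext_store"), nrow(store$patterns) >= 1L)
  use_seed(seed)
  lat_lo <- min(store$patterns[, store$D + seq_len(store$L)])
  lat_hi <- max(store$patterns[, store$D + seq_len(store$L)])
  Q <- cbind(matrix(stats::runif(n * store$D), n),
             matrix(stats::runif(n * store$L, lat_lo, lat_hi), n))
  r <- ext_retrieve(store, Q)
  lapply(seq_len(n), function(i) {
    parts <- split_combined(store, r$patterns[i, ])
    c(parts, list(combined = r$patterns[i, ], converged = r$converged[i]))
  })
}

#' Reconstruction-error and stored-detail sweep over encoding thresholds
#'
#' Encodes the same events (and recalls them from the same partial cues) at
#' each threshold, recording the mean number of stored sensory pixels per
#' trace and the mean recall reconstruction error, then rank-correlates both
#' with the threshold.
#'
#' @param vae The trained generative network.
#' @param images List of event images (typically scenes with novel-feature
#'   overlays).
#' @param thresholds Strictly increasing numeric vector (5 values in the
#'   reference setup).
#' @param partial_fraction Corruption fraction for the recall cues.
#' @param seed Optional integer seed (cue corruption).
#' @param latent_scale Conceptual-slot scale; estimated from `images` if NULL.
#' @param beta Hopfield inverse temperature.
#' @return A list: `rows` (data frame `threshold`, `mean_stored_pixels`,
#'   `mean_recon_error`), `rho_pixels`, `rho_error`.
#' @export
threshold_sweep <- function(vae, images, thresholds = c(0, 0.05, 0.1, 0.2, 0.4),
                            partial_fraction = 0.1, seed = NULL,
                            latent_scale = NULL, beta = 20) {
  if (any(diff(thresholds) <= 0)) {
    stop("`thresholds` must be strictly increasing")
  }
  use_seed(seed)
  partials <- lapply(images, corrupt_partial, fraction = partial_fraction)
  if (is.null(latent_scale)) latent_scale <- estimate_latent_scale(vae, images)

  # Decomposition pieces shared across thresholds: reconstructions, latents
  # and per-pixel error maps of events and cues.
  prep <- function(imgs) {
    X <- as_input_matrix(vae, imgs)
    mu <- forward_encoder(vae, X)$mu
    R <- vae_decode(vae, mu, as_image = FALSE)
    errs <- lapply(seq_along(imgs), function(i) {
      apply(abs(imgs[[i]] - unflatten_image(R[i, ], vae$config$input_shape)),
            c(1, 2), mean)
    })
    list(mu = mu, errs = errs)
  }
  ev <- prep(images)
  cue <- prep(partials)
  n <- length(images)
  ch <- vae$config$input_shape[3]

  rows <- lapply(thresholds, function(th) {
    store <- extended_store(vae, latent_scale = latent_scale, beta = beta)
    masks <- lapply(ev$errs, function(e) e > th)
    store$patterns <- t(vapply(seq_len(n), function(i) {
      sens <- images[[i]] * array(rep(masks[[i]], ch), dim(images[[i]]))
      trace_vector(store, sens, ev$mu[i, ])
    }, numeric(store$D + store$L)))
    Q <- t(vapply(seq_len(n), function(i) {
      m <- cue$errs[[i]] > th
      sens <- partials[[i]] * array(rep(m, ch), dim(partials[[i]]))
      trace_vector(store, sens, cue$mu[i, ])
    }, numeric(store$D + store$L)))
    r <- ext_retrieve(store, Q)
    err <- vapply(seq_len(n), function(i) {
      parts <- split_combined(store, r$patterns[i, ])
      final <- vae_decode(vae, parts$conceptual)
      keep <- abs(parts$sensory) > 1e-8
      final[keep] <- parts$sensory[keep]
      mean(abs(final - images[[i]]))
    }, numeric(1))
    data.frame(threshold = th,
               mean_stored_pixels = mean(vapply(masks, sum, numeric(1))),
               mean_recon_error = mean(err))
  })
  rows <- do.call(rbind, rows)
  list(rows = rows,
       rho_pixels = spearman_rho(rows$threshold, rows$mean_stored_pixels),
       rho_error = spearman_rho(rows$threshold, rows$mean_recon_error))
}
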