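# Latent-space operations used for recall, imagination and relational
# inference. All of them act on the posterior mean (deterministic recall).

#' Recall an image through the generative network
#'
#' Maps a (possibly partial) input to its latent posterior mean and decodes
#' it back to the sensory layer: `decode(encode(x)$mu)`.
#'
#' @param vae A trained `vae`.
#' @param partial Input image array, vector, or matrix of flattened rows.
#' @return The reconstruction, shaped like the input (array in, array out).
#' @export
recall_basic <- function(vae, partial) {
  X <- as_input_matrix(vae, partial)
  mu <- forward_encoder(vae, X)$mu
  Y <- vae_decode(vae, mu, as_image = FALSE)
  if (is.array(partial) && length(dim(partial)) == 3L) {
    unflatten_image(drop(Y), vae$config$input_shape)
  } else if (is.null(dim(partial))) {
    drop(Y)
  } else {
    Y
  }
}

#' Interpolate between two inputs in latent space
#'
#' Decodes `(1 - t) * zA + t * zB` for `steps` evenly spaced `t` in `[0, 1]`,
#' where `zA`, `zB` are posterior means; imagining items "between" two
#' memories.
#'
#' @param vae A trained `vae`.
#' @param xA,xB Input images.
#' @param steps Number of interpolation points (>= 2).
#' @return A list of `steps` decoded images.
#' @export
latent_interpolate <- function(vae, xA, xB, steps = 5L) {
  stopifnot(steps >= 2L)
  zA <- vae_encode(vae, xA)$mu
  zB <- vae_encode(vae, xB)$mu
  lapply(seq(0, 1, length.out = steps), function(t) {
    vae_decode(vae, (1 - t) * zA + t * zB)
  })
}

#' Relational inference by latent vector arithmetic
#'
#' Decodes `zA + (zB - zC)`: the relation between `xB` and `xC` applied to
#' `xA` ("what is to A as B is to C?").
#'
#' @param vae A trained `vae`.
#' @param xA,xB,xC Input images.
#' @return The decoded result image.
#' @export
latent_arithmetic <- function(vae, xA, xB, xC) {
  zA <- vae_encode(vae, xA)$mu
  zB <- vae_encode(vae, xB)$mu
  zC <- vae_encode(vae, xC)$mu
  vae_decode(vae, zA + zB - zC)
}

#' Fit a diagonal Gaussian to a set of latent vectors
#'
#' Per-dimension mean and standard deviation of the latent means of `x`;
#' used as the sampling distribution for imagination.
#'
#' @param vae A trained `vae`.
#' @param x Reference inputs.
#' @return A list with `mean` and `sd` vectors of length `latent_dim`.
#' @export
latent_distribution <- function(vae, x) {
  mu <- forward_encoder(vae, as_input_matrix(vae, x))$mu
  list(mean = colMeans(mu), sd = pmax(apply(mu, 2L, stats::sd), 1e-6))
}

#' Imagine an item from a semantic category
#'
#' Monte Carlo rejection sampling: draws latent vectors until the semantic
#' readout classifies one as the requested category, then decodes it. By
#' default draws come from `N(0, I)`; passing a [latent_distribution()]
#' samples from the model's aggregate latent distribution instead, which is
#' the useful choice when the KL pressure is weak and posteriors sit far
#' from the origin.
#'
#' @param vae A trained `vae`.
#' @param readout A [fit_readout()] classifier over latent vectors.
#' @param category Target category label.
#' @param budget Maximum number of draws.
#' @param seed Optional integer seed.
#' @param latent_stats Optional list with `mean` and `sd` vectors (see
#'   [latent_distribution()]).
#' @return A list of class `category_sample`: `found` (logical), `image`
#'   (decoded image or NULL), `z`, `tries`.
#' @export
sample_from_category <- function(vae, readout, category, budget = 1000L,
                                 seed = NULL, latent_stats = NULL) {
  stopifnot(budget >= 1L)
  use_seed(seed)
  L <- vae$config$latent_dim
  if (is.null(latent_stats)) latent_stats <- list(mean = rep(0, L),
                                                  sd = rep(1, L))
  for (i in seq_len(budget)) {
    z <- stats::rnorm(L, latent_stats$mean, latent_stats$sd)
    lab <- predict(readout, matrix(z, nrow = 1L))
    if (as.character(lab) == as.character(category)) {
      return(structure(list(found = TRUE, image = vae_decode(vae, z), z = z,
                            tries = i), class = "category_sample"))
    }
  }
  structure(list(found = FALSE, image = NULL, z = NULL, tries = budget),
            class = "category_sample")
}
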