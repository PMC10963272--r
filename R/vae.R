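# Variational autoencoder: the neocortical generative network. Feed-forward
# encoder (input -> hidden -> mu, logvar) and decoder (z -> hidden -> output)
# with ReLU hidden units, trained by backpropagation with the AMSGrad variant
# of Adam. Two configurations are used:
#   * images: MAE reconstruction loss, linear output clipped to [0, 1];
#   * bag-of-words: dropout on the input, no hidden layer, sigmoid output
#     with per-unit cross-entropy loss and L1 regularization on the output
#     weights (promoting sparse word predictions).
#
# The displayed loss is recon + kl_weight * KL, with recon the mean absolute
# (or cross-entropy) error per unit and KL = -0.5 * sum(1 + logvar - mu^2 -
# exp(logvar)) summed over latents. For optimization the KL term is
# normalized by the input dimension so that both terms are on a per-unit
# scale; with kl_weight = 1 this is the standard calibration that yields an
# informative latent space rather than posterior collapse.

LOGVAR_CLIP <- 20

#' VAE configuration
#'
#' @param input_shape Integer vector: `c(H, W, C)` for images or a single
#'   length for vector inputs (bag-of-words).
#' @param latent_dim Latent vector length (20 for images, 300 for
#'   bag-of-words in the reference setup).
#' @param hidden Integer vector of hidden layer sizes shared (mirrored) by
#'   encoder and decoder; `integer(0)` connects the input directly to the
#'   latent heads.
#' @param arch `"mlp"` (dense layers on the flat input) or `"patch"`
#'   (images only): the image is cut into non-overlapping square patches
#'   that share a linear embedding — a strided convolution — whose
#'   concatenated features feed the dense core, and the decoder mirrors
#'   this with a shared patch-decoding layer. The shared weights give the
#'   network translation-shared local features, which a flat dense encoder
#'   lacks.
#' @param patch_size Patch side length in pixels (must divide height and
#'   width; `arch = "patch"` only).
#' @param patch_embed Features per patch (`arch = "patch"` only).
#' @param learning_rate AMSGrad learning rate.
#' @param kl_weight Weight of the KL term.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without improvement).
#' @param min_delta Minimum improvement of the training objective counted as
#'   progress.
#' @param reconstruction_loss `"mae"` or `"bce"` (per-unit cross-entropy).
#' @param output_activation `"linear_clipped"` or `"sigmoid"`.
#' @param dropout_rate Input dropout rate (training only; bag-of-words).
#' @param l1_output_weight L1 penalty on the output layer weights.
#' @param batch_size Minibatch size.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(input_shape, latent_dim = 20L, hidden = c(256L),
                       arch = c("mlp", "patch"), patch_size = 8L,
                       patch_embed = 64L,
                       learning_rate = 0.001, kl_weight = 1,
                       max_epochs = 50L, patience = 5L, min_delta = 1e-4,
                       reconstruction_loss = c("mae", "bce"),
                       output_activation = c("linear_clipped", "sigmoid"),
                       dropout_rate = 0, l1_output_weight = 0,
                       batch_size = 64L) {
  reconstruction_loss <- match.arg(reconstruction_loss)
  output_activation <- match.arg(output_activation)
  arch <- match.arg(arch)
  stopifnot(latent_dim >= 1L, learning_rate > 0, kl_weight >= 0,
            max_epochs >= 1L, dropout_rate >= 0, dropout_rate < 1,
            l1_output_weight >= 0)
  if (arch == "patch") {
    if (length(input_shape) != 3L) stop("patch architecture needs an image input")
    if (any(input_shape[1:2] %% patch_size != 0)) {
      stop("`patch_size` must divide the image height and width")
    }
  }
  structure(list(arch = arch, patch_size = as.integer(patch_size),
                 patch_embed = as.integer(patch_embed),
                 input_shape = as.integer(input_shape),
                 input_dim = as.integer(prod(input_shape)),
                 latent_dim = as.integer(latent_dim),
                 hidden = as.integer(hidden),
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), min_delta = min_delta,
                 reconstruction_loss = reconstruction_loss,
                 output_activation = output_activation,
                 dropout_rate = dropout_rate,
                 l1_output_weight = l1_output_weight,
                 batch_size = as.integer(batch_size)),
            class = "vae_config")
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# --- patch front-end -------------------------------------------------------
# A non-overlapping patch grid makes the im2col of a strided convolution a
# pure index permutation: `patch_perm` maps the flat (row-major,
# channels-last) image vector onto patch-major order, `split_rows` turns a
# B x (P*d) matrix into a (B*P) x d matrix of per-patch rows (so one weight
# matrix is shared across all patches), and `merge_rows` inverts it. All
# three are permutations, so backpropagation just applies the inverse.

patch_geometry <- function(cfg) {
  h <- cfg$input_shape[1]; w <- cfg$input_shape[2]; ch <- cfg$input_shape[3]
  ps <- cfg$patch_size
  np_r <- h %/% ps; np_c <- w %/% ps
  P <- np_r * np_c
  pd <- ps * ps * ch
  perm <- integer(P * pd)
  i <- 1L
  for (pr in seq_len(np_r) - 1L) {
    for (pc in seq_len(np_c) - 1L) {
      for (r in seq_len(ps) - 1L) {
        for (cc in seq_len(ps) - 1L) {
          for (k in seq_len(ch) - 1L) {
            perm[i] <- ((pr * ps + r) * w + (pc * ps + cc)) * ch + k + 1L
            i <- i + 1L
          }
        }
      }
    }
  }
  invperm <- integer(length(perm))
  invperm[perm] <- seq_along(perm)
  list(P = P, pd = pd, perm = perm, invperm = invperm)
}

# Both reshapes are fixed permutations of the underlying data; the gather
# index is computed once per (B, P, d, permutation) and cached, so each call
# is a single indexed copy instead of a chain of transposes.
.reshape_cache <- new.env(parent = emptyenv())

reshape_tag <- function(colperm) {
  if (is.null(colperm)) return("0")
  paste0(length(colperm), "x", colperm[1L], "x",
         sum(as.numeric(colperm)) %% 97777)
}

split_rows <- function(M, P, colperm = NULL) {
  B <- nrow(M); d <- ncol(M) %/% P
  key <- paste0("s", B, "_", P, "_", d, "_", reshape_tag(colperm))
  idx <- .reshape_cache[[key]]
  if (is.null(idx)) {
    k <- seq_len(B * P * d) - 1L
    j <- k %/% (B * P)                 # 0-based output column
    r <- k %% (B * P)
    b <- r %/% P
    p <- r %% P
    col <- p * d + j + 1L
    if (!is.null(colperm)) col <- colperm[col]
    idx <- (col - 1L) * B + b + 1L
    .reshape_cache[[key]] <- idx
  }
  matrix(M[idx], B * P, d)
}

merge_rows <- function(Mp, P, colperm = NULL) {
  d <- ncol(Mp); B <- nrow(Mp) %/% P
  key <- paste0("m", B, "_", P, "_", d, "_", reshape_tag(colperm))
  idx <- .reshape_cache[[key]]
  if (is.null(idx)) {
    k <- seq_len(B * P * d) - 1L
    cc <- k %/% B + 1L                 # 1-based output column
    b <- k %% B
    c2 <- if (is.null(colperm)) cc else colperm[cc]
    p <- (c2 - 1L) %/% d
    j <- (c2 - 1L) %% d
    idx <- j * (B * P) + b * P + p + 1L
    .reshape_cache[[key]] <- idx
  }
  matrix(Mp[idx], B, P * d)
}

#' Initialize an untrained VAE
#'
#' @param config A [vae_config()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `vae` holding weights and the config.
#' @export
vae_new <- function(config, seed = NULL) {
  stopifnot(inherits(config, "vae_config"))
  use_seed(seed)
  D <- config$input_dim; L <- config$latent_dim; H <- config$hidden
  geom <- NULL
  params <- list()
  core_in <- D
  if (config$arch == "patch") {
    geom <- patch_geometry(config)
    E <- config$patch_embed
    params$Wp <- glorot(geom$pd, E); params$bp <- numeric(E)
    core_in <- geom$P * E
  }
  enc_sizes <- c(core_in, H)
  dec_sizes <- c(L, rev(H))
  for (i in seq_along(H)) {
    params[[paste0("We", i)]] <- glorot(enc_sizes[i], enc_sizes[i + 1])
    params[[paste0("be", i)]] <- numeric(enc_sizes[i + 1])
  }
  top <- enc_sizes[length(enc_sizes)]
  params$Wmu <- glorot(top, L); params$bmu <- numeric(L)
  params$Wlv <- glorot(top, L); params$blv <- numeric(L)
  for (i in seq_along(H)) {
    params[[paste0("Wd", i)]] <- glorot(dec_sizes[i], dec_sizes[i + 1])
    params[[paste0("bd", i)]] <- numeric(dec_sizes[i + 1])
  }
  bot <- dec_sizes[length(dec_sizes)]
  if (config$arch == "patch") {
    E <- config$patch_embed
    params$Wg <- glorot(bot, geom$P * E); params$bg <- numeric(geom$P * E)
    params$Wq <- glorot(E, geom$pd); params$bq <- numeric(geom$pd)
  } else {
    params$Wo <- glorot(bot, D); params$bo <- numeric(D)
  }
  structure(list(config = config, params = params, geom = geom,
                 trained = FALSE),
            class = "vae")
}

#' @export
print.vae <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("VAE: input %s, hidden [%s], latent %d, loss %s (%strained)\n",
              paste(cfg$input_shape, collapse = "x"),
              paste(cfg$hidden, collapse = ", "), cfg$latent_dim,
              cfg$reconstruction_loss, if (x$trained) "" else "un"))
  invisible(x)
}

add_bias <- function(M, b) M + rep(b, each = nrow(M))
relu <- function(x) {x[x < 0] <- 0; x}
sigmoid <- function(x) 1 / (1 + exp(-x))

# Coerce inputs to a batch matrix of flattened rows.
as_input_matrix <- function(vae, x) {
  D <- vae$config$input_dim
  if (is.array(x) && length(dim(x)) == 3L) {
    if (!identical(dim(x), as.integer(vae$config$input_shape))) {
      stop("input shape does not match the VAE's input_shape")
    }
    return(matrix(flatten_image(x), nrow = 1L))
  }
  if (is.list(x)) x <- t(vapply(x, flatten_image, numeric(D)))
  if (is.null(dim(x))) {
    if (length(x) != D) stop("input length does not match the VAE's input_dim")
    return(matrix(as.numeric(x), nrow = 1L))
  }
  x <- as.matrix(x)
  if (ncol(x) != D) stop("input width does not match the VAE's input_dim")
  x
}

# Forward pass through the encoder; returns cached activations.
forward_encoder <- function(vae, X) {
  p <- vae$params; H <- vae$config$hidden
  patch <- NULL
  if (vae$config$arch == "patch") {
    g <- vae$geom
    XP <- split_rows(X, g$P, g$perm)
    H0p <- relu(add_bias(XP %*% p$Wp, p$bp))
    X <- merge_rows(H0p, g$P)
    patch <- list(XP = XP, H0p = H0p)
  }
  acts <- list(X)
  A <- X
  for (i in seq_along(H)) {
    A <- relu(add_bias(A %*% p[[paste0("We", i)]], p[[paste0("be", i)]]))
    acts[[i + 1L]] <- A
  }
  mu <- add_bias(A %*% p$Wmu, p$bmu)
  lv_pre <- add_bias(A %*% p$Wlv, p$blv)
  lv <- pmin(pmax(lv_pre, -LOGVAR_CLIP), LOGVAR_CLIP)
  list(acts = acts, mu = mu, lv = lv, lv_pre = lv_pre, patch = patch)
}

# Forward pass through the decoder; returns cached activations.
forward_decoder <- function(vae, Z) {
  p <- vae$params; H <- vae$config$hidden
  acts <- list(Z)
  A <- Z
  for (i in seq_along(H)) {
    A <- relu(add_bias(A %*% p[[paste0("Wd", i)]], p[[paste0("bd", i)]]))
    acts[[i + 1L]] <- A
  }
  patch <- NULL
  if (vae$config$arch == "patch") {
    g <- vae$geom
    G <- relu(add_bias(A %*% p$Wg, p$bg))
    Gp <- split_rows(G, g$P)
    Yp <- add_bias(Gp %*% p$Wq, p$bq)
    pre <- merge_rows(Yp, g$P, g$invperm)
    patch <- list(G = G, Gp = Gp)
  } else {
    pre <- add_bias(A %*% p$Wo, p$bo)
  }
  Y <- if (vae$config$output_activation == "sigmoid") sigmoid(pre) else pre
  list(acts = acts, pre = pre, Y = Y, patch = patch)
}

#' Encode an input to its latent posterior
#'
#' Deterministic given the weights: returns the posterior mean and
#' log-variance (clipped to `[-20, 20]`).
#'
#' @param vae A [vae_new()] object.
#' @param x An image array, flattened vector, or matrix of flattened rows.
#' @return For a single input, a list of class `latent_posterior` with `mu`
#'   and `logvar` vectors; for a batch, matrices with one row per input.
#' @export
vae_encode <- function(vae, x) {
  X <- as_input_matrix(vae, x)
  fe <- forward_encoder(vae, X)
  if (nrow(X) == 1L) {
    structure(list(mu = drop(fe$mu), logvar = drop(fe$lv)),
              class = "latent_posterior")
  } else {
    structure(list(mu = fe$mu, logvar = fe$lv), class = "latent_posterior")
  }
}

#' Sample a latent vector from a posterior
#'
#' Reparameterization: `z = mu + exp(logvar / 2) * eps`, `eps ~ N(0, I)`.
#'
#' @param posterior A `latent_posterior` from [vae_encode()].
#' @param seed Optional integer seed.
#' @return A latent vector (or matrix for batch posteriors).
#' @export
vae_sample_latent <- function(posterior, seed = NULL) {
  use_seed(seed)
  mu <- posterior$mu; lv <- posterior$logvar
  eps <- stats::rnorm(length(mu))
  if (!is.null(dim(mu))) eps <- matrix(eps, nrow(mu), ncol(mu))
  mu + exp(lv / 2) * eps
}

#' Decode latent vectors to the sensory layer
#'
#' @param vae A `vae` object.
#' @param z Latent vector of length `latent_dim`, or a matrix of rows.
#' @param as_image Reshape a single decoded vector to the input array shape
#'   when the VAE is an image model (default TRUE).
#' @return Output in `[0, 1]` per unit: an image array, vector, or matrix.
#' @export
vae_decode <- function(vae, z, as_image = TRUE) {
  L <- vae$config$latent_dim
  single <- is.null(dim(z))
  if (single) {
    if (length(z) != L) stop("latent length does not match latent_dim")
    z <- matrix(z, nrow = 1L)
  } else if (ncol(z) != L) stop("latent width does not match latent_dim")
  Y <- forward_decoder(vae, z)$Y
  if (vae$config$output_activation == "linear_clipped") Y <- clip01(Y)
  if (single) {
    y <- drop(Y)
    if (as_image && length(vae$config$input_shape) == 3L) {
      return(unflatten_image(y, vae$config$input_shape))
    }
    return(y)
  }
  Y
}

#' VAE loss (reconstruction + KL)
#'
#' `recon` is the mean absolute error per unit (or per-unit cross-entropy);
#' `kl = -0.5 * sum(1 + logvar - mu^2 - exp(logvar))` summed over latents
#' (averaged over the batch for matrix posteriors); `total = recon +
#' kl_weight * kl`.
#'
#' @param x Target (image array, vector, or matrix of rows).
#' @param x_hat Reconstruction of the same shape.
#' @param posterior A `latent_posterior`.
#' @param kl_weight KL weight.
#' @param reconstruction `"mae"` or `"bce"`.
#' @return A list with `total`, `recon`, `kl`.
#' @export
vae_loss <- function(x, x_hat, posterior, kl_weight = 1,
                     reconstruction = c("mae", "bce")) {
  reconstruction <- match.arg(reconstruction)
  if (is.array(x) && length(dim(x)) == 3L) x <- flatten_image(x)
  if (is.array(x_hat) && length(dim(x_hat)) == 3L) x_hat <- flatten_image(x_hat)
  stopifnot(length(x) == length(x_hat))
  recon <- if (reconstruction == "mae") {
    mean(abs(x - x_hat))
  } else {
    eps <- 1e-7
    y <- pmin(pmax(x_hat, eps), 1 - eps)
    -mean(x * log(y) + (1 - x) * log(1 - y))
  }
  mu <- posterior$mu; lv <- posterior$logvar
  if (is.null(dim(mu))) {
    kl <- -0.5 * sum(1 + lv - mu^2 - exp(lv))
  } else {
    kl <- mean(-0.5 * rowSums(1 + lv - mu^2 - exp(lv)))
  }
  list(total = recon + kl_weight * kl, recon = recon, kl = kl)
}

# One training step on a batch; returns gradients and the batch losses.
vae_backward <- function(vae, X, target, eps, dropmask = NULL) {
  cfg <- vae$config; p <- vae$params
  nH <- length(cfg$hidden)
  B <- nrow(X); D <- cfg$input_dim
  Xin <- if (is.null(dropmask)) X else X * dropmask
  fe <- forward_encoder(vae, Xin)
  Z <- fe$mu + exp(fe$lv / 2) * eps
  fd <- forward_decoder(vae, Z)
  Y <- fd$Y

  recon <- if (cfg$reconstruction_loss == "mae") {
    mean(abs(target - Y))
  } else {
    e <- 1e-7; yc <- pmin(pmax(Y, e), 1 - e)
    -mean(target * log(yc) + (1 - target) * log(1 - yc))
  }
  kl_vec <- -0.5 * rowSums(1 + fe$lv - fe$mu^2 - exp(fe$lv))
  kl <- mean(kl_vec)
  kl_scale <- cfg$kl_weight / D
  out_W <- if (cfg$arch == "patch") p$Wq else p$Wo
  objective <- recon + kl_scale * kl +
    cfg$l1_output_weight * sum(abs(out_W))

  grads <- list()
  # Output layer: d objective / d pre-activation. For MAE the output is
  # linear; for BCE the sigmoid and cross-entropy combine to (Y - target).
  dPre <- if (cfg$reconstruction_loss == "mae") {
    sign(Y - target) / (B * D)
  } else {
    (Y - target) / (B * D)
  }
  Adec <- fd$acts[[nH + 1L]]
  if (cfg$arch == "patch") {
    g <- vae$geom
    dYp <- split_rows(dPre, g$P, g$perm)
    grads$Wq <- crossprod(fd$patch$Gp, dYp) +
      cfg$l1_output_weight * sign(p$Wq)
    grads$bq <- colSums(dYp)
    dG <- merge_rows(tcrossprod(dYp, p$Wq), g$P) * (fd$patch$G > 0)
    grads$Wg <- crossprod(Adec, dG)
    grads$bg <- colSums(dG)
    dA <- tcrossprod(dG, p$Wg)
  } else {
    grads$Wo <- crossprod(Adec, dPre) + cfg$l1_output_weight * sign(p$Wo)
    grads$bo <- colSums(dPre)
    dA <- tcrossprod(dPre, p$Wo)
  }
  for (i in rev(seq_len(nH))) {
    dA <- dA * (fd$acts[[i + 1L]] > 0)
    grads[[paste0("Wd", i)]] <- crossprod(fd$acts[[i]], dA)
    grads[[paste0("bd", i)]] <- colSums(dA)
    dA <- tcrossprod(dA, p[[paste0("Wd", i)]])
  }
  dZ <- dA
  # KL gradients (normalized), plus reparameterized reconstruction path.
  clipmask <- (abs(fe$lv_pre) < LOGVAR_CLIP) * 1
  dMu <- dZ + kl_scale * fe$mu / B
  dLv <- (dZ * eps * 0.5 * exp(fe$lv / 2) +
            kl_scale * 0.5 * (exp(fe$lv) - 1) / B) * clipmask
  Aenc <- fe$acts[[nH + 1L]]
  grads$Wmu <- crossprod(Aenc, dMu); grads$bmu <- colSums(dMu)
  grads$Wlv <- crossprod(Aenc, dLv); grads$blv <- colSums(dLv)
  dA <- tcrossprod(dMu, p$Wmu) + tcrossprod(dLv, p$Wlv)
  for (i in rev(seq_len(nH))) {
    dA <- dA * (fe$acts[[i + 1L]] > 0)
    grads[[paste0("We", i)]] <- crossprod(fe$acts[[i]], dA)
    grads[[paste0("be", i)]] <- colSums(dA)
    dA <- tcrossprod(dA, p[[paste0("We", i)]])
  }
  if (cfg$arch == "patch") {
    g <- vae$geom
    dH0p <- split_rows(dA, g$P) * (fe$patch$H0p > 0)
    grads$Wp <- crossprod(fe$patch$XP, dH0p)
    grads$bp <- colSums(dH0p)
  }
  list(grads = grads, recon = recon, kl = kl, objective = objective)
}

amsgrad_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       vhat = lapply(params, function(p) p * 0),
       t = 0L)
}

amsgrad_step <- function(params, grads, state, lr, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(grads)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    state$vhat[[k]] <- pmax(state$vhat[[k]], state$v[[k]])
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$vhat[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train a VAE
#'
#' Minibatch stochastic gradient descent with the AMSGrad variant of Adam and
#' early stopping on the training objective (patience and minimum improvement
#' from the config). Deterministic given `seed`.
#'
#' @param vae A `vae` object (its config controls training).
#' @param data Training data: matrix of flattened rows, list of image arrays,
#'   or a single array.
#' @param seed Optional integer seed (shuffling, dropout, latent noise).
#' @param eval_fn Optional `function(vae, epoch)` returning a named list of
#'   numbers appended to the per-epoch log (used for the decoding-accuracy
#'   curve during consolidation).
#' @param verbose Print per-epoch losses.
#' @return A list: `vae` (trained), `log` (data frame with one row per epoch:
#'   reconstruction error, KL, objective, and any `eval_fn` columns).
#' @export
vae_train <- function(vae, data, seed = NULL, eval_fn = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(vae, "vae"))
  X <- as_input_matrix(vae, data)
  if (nrow(X) < 1L) stop("training data is empty")
  cfg <- vae$config
  use_seed(seed)
  target <- if (cfg$reconstruction_loss == "bce") pmin(X, 1) else X
  state <- amsgrad_init(vae$params)
  log_rows <- vector("list", cfg$max_epochs)
  best <- Inf; wait <- 0L
  n <- nrow(X)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_recon <- 0; ep_kl <- 0; ep_obj <- 0; nb <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Tb <- target[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * cfg$latent_dim),
                    length(idx), cfg$latent_dim)
      dropmask <- NULL
      if (cfg$dropout_rate > 0) {
        keep <- 1 - cfg$dropout_rate
        dropmask <- matrix(stats::rbinom(length(Xb), 1L, keep) / keep,
                           nrow(Xb), ncol(Xb))
      }
      bw <- vae_backward(vae, Xb, Tb, eps, dropmask)
      if (!is.finite(bw$objective)) {
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      }
      upd <- amsgrad_step(vae$params, bw$grads, state, cfg$learning_rate)
      vae$params <- upd$params
      state <- upd$state
      ep_recon <- ep_recon + bw$recon
      ep_kl <- ep_kl + bw$kl
      ep_obj <- ep_obj + bw$objective
      nb <- nb + 1L
    }
    row <- list(epoch = epoch, recon = ep_recon / nb, kl = ep_kl / nb,
                objective = ep_obj / nb)
    if (!is.null(eval_fn)) {
      vae$trained <- TRUE
      row <- c(row, eval_fn(vae, epoch))
    }
    log_rows[[epoch]] <- row
    if (verbose) {
      message(sprintf("epoch %d: recon %.5f kl %.3f", epoch, row$recon,
                      row$kl))
    }
    if (row$objective < best - cfg$min_delta) {
      best <- row$objective; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  vae$trained <- TRUE
  log <- do.call(rbind, lapply(log_rows[!vapply(log_rows, is.null, TRUE)],
                               function(r) as.data.frame(r)))
  list(vae = vae, log = log)
}
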