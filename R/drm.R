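# DRM false-memory simulation. A bag-of-words VAE (dropout input -> 300
# latents -> sigmoid output with L1) learns word co-occurrence statistics
# from the corpus. Each study list is encoded in the extended store as a
# combined trace: a one-hot "id_n" unit (the unique spatiotemporal context,
# stored veridically in the sensory slot) plus the VAE's latent
# representation of the list's count vector (the conceptual slot). Cueing
# with id_n retrieves the trace; decoding the latents yields per-word scores,
# and words scoring > 0.5 are "recalled". The lure is recalled when the
# gist-level latents generate it, although it was never studied.

#' Filter a corpus by document frequency
#'
#' Restricts the vocabulary to words with document frequency in
#' `[min_df, max_df]`; count vectors are re-projected and DRM-list words
#' outside the retained vocabulary are dropped.
#'
#' @param corpus A `corpus` object.
#' @param min_df,max_df Document-frequency bounds (fractions of documents).
#' @return The filtered `corpus`.
#' @export
preprocess_corpus <- function(corpus, min_df = 0.0005, max_df = 0.10) {
  stopifnot(inherits(corpus, "corpus"), min_df >= 0, min_df < max_df,
            max_df <= 1)
  df <- colMeans(corpus$counts > 0)
  keep <- df >= min_df & df <= max_df
  if (!any(keep)) stop("document-frequency filter removed every word")
  corpus$vocabulary <- corpus$vocabulary[keep]
  corpus$counts <- corpus$counts[, keep, drop = FALSE]
  corpus$drm_lists <- lapply(corpus$drm_lists, function(l) {
    list(words = intersect(l$words, corpus$vocabulary), lure = l$lure)
  })
  corpus
}

#' Default bag-of-words VAE configuration
#'
#' Dropout on the input, no hidden layer, 300 latents, sigmoid output with
#' L1 regularization and per-unit cross-entropy loss.
#'
#' @param vocab_size Vocabulary length after filtering.
#' @param latent_dim Latent dimension.
#' @param dropout_rate Input dropout rate.
#' @param l1_output_weight L1 penalty on output weights.
#' @param max_epochs Training epochs.
#' @return A [vae_config()].
#' @export
bow_vae_config <- function(vocab_size, latent_dim = 300L, dropout_rate = 0.3,
                           l1_output_weight = 1e-5, kl_weight = 0.05,
                           max_epochs = 50L) {
  vae_config(input_shape = vocab_size, latent_dim = latent_dim,
             hidden = integer(0), reconstruction_loss = "bce",
             output_activation = "sigmoid", dropout_rate = dropout_rate,
             l1_output_weight = l1_output_weight, kl_weight = kl_weight,
             max_epochs = max_epochs)
}

#' Train the bag-of-words generative network on a corpus
#'
#' @param corpus A (filtered) `corpus`.
#' @param config A [vae_config()]; defaults to [bow_vae_config()].
#' @param seed Optional integer seed.
#' @return A list: `vae`, `log`.
#' @export
train_bow_vae <- function(corpus, config = NULL, seed = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  if (is.null(config)) config <- bow_vae_config(length(corpus$vocabulary))
  use_seed(seed)
  vae <- vae_new(config, seed = sample.int(2^31 - 1, 1L))
  vae_train(vae, corpus$counts, seed = sample.int(2^31 - 1, 1L))
}

#' Encode a word list into the bag-of-words latent space
#'
#' Studied list items are attended and rehearsed, unlike incidental corpus
#' occurrences, so each studied word is encoded with a fixed exposure weight
#' (count `exposure` instead of 1). The total evidence driving the posterior
#' thus remains proportional to the number of studied words, while a single
#' studied word still provides more evidence than one incidental token.
#'
#' @param vae A trained bag-of-words `vae`.
#' @param corpus The (filtered) training `corpus`.
#' @param words Character vector of studied words.
#' @param exposure Corpus-token equivalents per studied word (default 1.25).
#' @return The latent posterior mean.
#' @export
encode_word_list <- function(vae, corpus, words, exposure = 1.25) {
  counts <- words_to_counts(words, corpus$vocabulary)
  vae_encode(vae, counts * exposure)$mu
}

# Build the extended store holding DRM traces. Each trace's sensory slot has
# length vocab + n_lists (id one-hot); the conceptual slot holds the scaled
# latents of the studied words' count vector.
drm_store <- function(vae, corpus, study_lists, latent_scale, beta = 20) {
  V <- length(corpus$vocabulary)
  n <- length(study_lists)
  L <- vae$config$latent_dim
  D <- V + n
  patterns <- matrix(0, n, D + L)
  for (i in seq_len(n)) {
    mu <- encode_word_list(vae, corpus, study_lists[[i]])
    patterns[i, V + i] <- 1
    patterns[i, D + seq_len(L)] <- mu / latent_scale
  }
  structure(list(patterns = patterns, D = D, L = L, V = V, n_lists = n,
                 latent_scale = latent_scale, beta = beta,
                 input_shape = D),
            class = c("drm_store", "ext_store"))
}

# Cue a DRM store with id_n and decode the retrieved latents to word scores.
drm_recall_scores <- function(store, vae, n) {
  q <- numeric(store$D + store$L)
  q[store$V + n] <- 1
  r <- ext_retrieve(store, matrix(q, nrow = 1L))
  z <- r$patterns[1L, store$D + seq_len(store$L)] * store$latent_scale
  vae_decode(vae, z, as_image = FALSE)
}

#' Run the DRM recall experiment
#'
#' Encodes each study list as an id + latents trace, cues each trace with its
#' id unit, and thresholds the decoded word scores at `score_threshold`.
#'
#' @param corpus A filtered `corpus` whose `drm_lists` provide the stimuli.
#' @param vae A trained bag-of-words `vae` (from [train_bow_vae()]).
#' @param score_threshold Recall threshold on the decoded scores.
#' @param latent_scale Conceptual-slot scale; estimated from the study lists
#'   if NULL.
#' @return An object of class `drm_result`: per list, the recalled word set,
#'   `lure_recalled`, `studied_recalled` (hits), `intrusions` (recalled,
#'   neither studied nor lure), plus `lure_rate` overall.
#' @export
drm_experiment <- function(corpus, vae, score_threshold = 0.5,
                           latent_scale = NULL) {
  stopifnot(inherits(corpus, "corpus"), inherits(vae, "vae"))
  if (!vae$trained) stop("the bag-of-words VAE must be trained first")
  lists <- lapply(corpus$drm_lists, `[[`, "words")
  if (is.null(latent_scale)) {
    latent_scale <- drm_latent_scale(vae, corpus, lists)
  }
  store <- drm_store(vae, corpus, lists, latent_scale)
  per_list <- lapply(seq_along(lists), function(i) {
    scores <- drm_recall_scores(store, vae, i)
    recalled <- corpus$vocabulary[scores > score_threshold]
    lure <- corpus$drm_lists[[i]]$lure
    list(recalled = recalled,
         lure = lure,
         lure_recalled = lure %in% recalled,
         studied_recalled = intersect(recalled, lists[[i]]),
         forgotten = setdiff(lists[[i]], recalled),
         intrusions = setdiff(recalled, c(lists[[i]], lure)),
         scores = scores)
  })
  structure(list(per_list = per_list,
                 lure_rate = mean(vapply(per_list, `[[`, TRUE,
                                         "lure_recalled"))),
            class = "drm_result")
}

#' @export
print.drm_result <- function(x, ...) {
  n <- length(x$per_list)
  cat(sprintf("DRM recall over %d lists: lure recalled in %d (%.0f%%)\n",
              n, sum(vapply(x$per_list, `[[`, TRUE, "lure_recalled")),
              100 * x$lure_rate))
  invisible(x)
}

# Conceptual-slot scale for DRM traces: the maximum latent L2 norm over the
# study lists. The id cue is a single unit of amplitude 1, so retrieval is
# only guaranteed to complete to the cued trace if the traces' conceptual
# norms (which enter the MHN's energy bias) differ by less than the id
# overlap; normalizing every conceptual vector to norm <= 1 ensures that.
drm_latent_scale <- function(vae, corpus, lists) {
  mus <- t(vapply(lists, function(w) encode_word_list(vae, corpus, w),
                  numeric(vae$config$latent_dim)))
  s <- max(sqrt(rowSums(mus^2)))
  if (s <= 0) 1 else s
}

#' Lure recall probability as a function of studied list length
#'
#' For each length `n`, encodes `n`-word random subsets of every DRM list
#' (`reps` subsets per list), cues with the id unit, and records whether the
#' lure is recalled; the probabilities are rank-correlated with length.
#'
#' @param corpus A filtered `corpus`.
#' @param vae A trained bag-of-words `vae`.
#' @param lengths Studied-length conditions (default 1 to 12).
#' @param reps Random subsets per list and length.
#' @param score_threshold Recall threshold on decoded scores.
#' @param seed Optional integer seed.
#' @return A list: `table` (data frame `length`, `lure_probability`), `rho`
#'   (Spearman correlation of length vs probability).
#' @export
lure_rate_vs_length <- function(corpus, vae, lengths = 1:12, reps = 20L,
                                score_threshold = 0.5, seed = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  use_seed(seed)
  full_lists <- lapply(corpus$drm_lists, `[[`, "words")
  lures <- vapply(corpus$drm_lists, `[[`, "", "lure")
  usable <- lengths(full_lists) >= max(lengths)
  if (!all(usable)) {
    warning(sprintf("%d lists shorter than the longest condition skipped",
                    sum(!usable)))
    full_lists <- full_lists[usable]
    lures <- lures[usable]
  }
  latent_scale <- drm_latent_scale(vae, corpus, full_lists)
  rows <- lapply(lengths, function(n) {
    hits <- 0L; total <- 0L
    for (rep_i in seq_len(reps)) {
      subsets <- lapply(full_lists, function(w) sample(w, n))
      store <- drm_store(vae, corpus, subsets, latent_scale)
      for (i in seq_along(subsets)) {
        scores <- drm_recall_scores(store, vae, i)
        hits <- hits + (scores[match(lures[i], corpus$vocabulary)] >
                          score_threshold)
        total <- total + 1L
      }
    }
    data.frame(length = n, lure_probability = hits / total)
  })
  tab <- do.call(rbind, rows)
  rho <- if (nrow(tab) >= 3L) {
    spearman_rho(tab$length, tab$lure_probability)
  } else {
    NA_real_
  }
  list(table = tab, rho = rho)
}
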