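# Topic-structured synthetic text corpus for the DRM false-memory pipeline.
# A mixture-of-topics unigram model: each document draws most of its tokens
# from one topic's word set (in which a designated "lure" word has high
# probability) and the rest from a shared background vocabulary. DRM study
# lists are drawn from a topic's words *excluding* its lure, so the lure is
# semantically central to the list but never studied.

#' Corpus generator configuration
#'
#' @param n_topics Number of topics (>= 20; one DRM list per topic).
#' @param words_per_topic Topic-specific words per topic (first is the lure).
#' @param n_background Shared background words.
#' @param n_docs Documents to generate.
#' @param doc_length Mean document length (Poisson).
#' @param topic_weight Fraction of a document's tokens drawn from its topic.
#' @param lure_prob Range (length 2) of the lure's probability within its
#'   topic's word distribution; each topic draws its own value uniformly
#'   from this range, emulating the wide between-list variation in
#'   associative strength of real DRM lists. The remaining topic mass is
#'   spread over the other topic words with a mild rank decay.
#' @param list_length Words per DRM study list.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_topics = 20L, words_per_topic = 25L,
                          n_background = 100L, n_docs = 2000L,
                          doc_length = 40, topic_weight = 0.7,
                          lure_prob = c(0.02, 0.4), list_length = 15L) {
  if (length(lure_prob) == 1L) lure_prob <- rep(lure_prob, 2L)
  stopifnot(n_topics >= 20L, words_per_topic > list_length,
            list_length >= 1L, topic_weight > 0, topic_weight < 1,
            all(lure_prob > 0), all(lure_prob < 1),
            lure_prob[1] <= lure_prob[2])
  structure(as.list(environment()), class = "corpus_config")
}

#' Generate a synthetic topic-structured corpus
#'
#' @param config A [corpus_config()].
#' @param seed Optional integer seed.
#' @return An object of class `corpus`: `vocabulary` (character),
#'   `counts` (documents x vocabulary integer matrix) and `drm_lists`
#'   (list of `list(words, lure)`; the lure is absent from its own list).
#' @export
generate_corpus <- function(config = corpus_config(), seed = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  if (config$words_per_topic - 1L < config$list_length) {
    stop("topic smaller than requested list length")
  }
  use_seed(seed)
  K <- config$n_topics
  W <- config$words_per_topic
  topic_words <- lapply(seq_len(K), function(k) {
    sprintf("t%02d_w%02d", k, seq_len(W))
  })
  background <- sprintf("bg_%03d", seq_len(config$n_background))
  vocabulary <- c(unlist(topic_words), background)
  V <- length(vocabulary)

  # Within-topic distribution: lure first with topic-specific mass, the
  # remaining mass over the other words with 1/sqrt(rank) decay.
  wt <- 1 / sqrt(seq_len(W - 1L))
  lure_mass <- stats::runif(K, config$lure_prob[1], config$lure_prob[2])
  topic_p_for <- function(k) {
    c(lure_mass[k], (1 - lure_mass[k]) * wt / sum(wt))
  }

  counts <- matrix(0L, config$n_docs, V)
  doc_topic <- sample.int(K, config$n_docs, replace = TRUE)
  bg_p <- 1 / sqrt(seq_len(config$n_background))
  for (d in seq_len(config$n_docs)) {
    len <- max(5L, stats::rpois(1L, config$doc_length))
    n_top <- stats::rbinom(1L, len, config$topic_weight)
    k <- doc_topic[d]
    ids <- c(
      (k - 1L) * W + sample.int(W, n_top, replace = TRUE,
                                prob = topic_p_for(k)),
      K * W + sample.int(config$n_background, len - n_top, replace = TRUE,
                         prob = bg_p)
    )
    tab <- tabulate(ids, nbins = V)
    counts[d, ] <- tab
  }

  drm_lists <- lapply(seq_len(K), function(k) {
    pool <- topic_words[[k]][-1L]           # exclude the lure
    list(words = sample(pool, config$list_length),
         lure = topic_words[[k]][1L])
  })

  structure(list(vocabulary = vocabulary, counts = counts,
                 drm_lists = drm_lists, doc_topic = doc_topic,
                 config = config),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("corpus: %d documents, %d words, %d DRM lists\n",
              nrow(x$counts), length(x$vocabulary), length(x$drm_lists)))
  invisible(x)
}

#' Document frequency of each vocabulary word
#'
#' @param corpus A `corpus` object.
#' @return Named numeric vector of fractions of documents containing each word.
#' @export
document_frequency <- function(corpus) {
  df <- colMeans(corpus$counts > 0)
  names(df) <- corpus$vocabulary
  df
}

#' Convert a word list to a count vector over a vocabulary
#'
#' Words absent from the vocabulary are dropped.
#'
#' @param words Character vector.
#' @param vocabulary Character vector defining vector positions.
#' @return Integer vector of length `length(vocabulary)`.
#' @export
words_to_counts <- function(words, vocabulary) {
  idx <- match(words, vocabulary)
  tabulate(idx[!is.na(idx)], nbins = length(vocabulary))
}
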