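# Continuous modern Hopfield network (MHN): one-shot autoassociative storage
# with softmax attractor retrieval. With stored patterns X (M x D), inverse
# temperature beta and query q, one update is
#
#     q <- t(X) %*% softmax(beta * (X %*% q - ||x_m||^2 / 2))
#
# The per-memory bias -||x_m||^2 / 2 makes the softmax argument equal (up to
# a query-only constant) to the negative squared Euclidean distance between
# the cue and each stored pattern, so pattern completion retrieves the
# *closest* stored memory rather than the one with the largest raw inner
# product (unnormalized [0, 1] patterns differ widely in norm, and a plain
# dot product would be biased towards bright memories). At high beta the
# softmax is near one-hot and attractors are the individual stored rows; the
# softmax weights can be read as activations of M "memory units" binding the
# D feature units of each event, each with its own excitability bias.
# Random-noise queries retrieve stored memories, which models replay.

#' Store patterns in a modern Hopfield network
#'
#' Storage is one-shot: the store holds exact copies of the patterns, with no
#' iterative learning.
#'
#' @param patterns An M x D numeric matrix (rows are flattened events), or a
#'   list of equal-length numeric vectors.
#' @param beta Positive inverse temperature (default 20; high enough that
#'   attractors are individual memories).
#' @param value_range Length-2 numeric `c(lo, hi)`: the per-dimension value
#'   range used when sampling noise queries for replay.
#' @return An object of class `hopfield_store`.
#' @export
hopfield_store <- function(patterns, beta = 20, value_range = c(0, 1)) {
  if (is.list(patterns)) {
    lens <- lengths(patterns)
    if (length(patterns) == 0L) stop("at least one pattern is required")
    if (length(unique(lens)) != 1L) stop("patterns must have equal lengths")
    patterns <- do.call(rbind, patterns)
  }
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1L) stop("at least one pattern is required")
  if (!all(is.finite(patterns))) stop("stored patterns must be finite")
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be positive")
  stopifnot(length(value_range) == 2L, value_range[1] < value_range[2])
  structure(list(patterns = patterns, beta = beta, value_range = value_range,
                 norms2 = rowSums(patterns^2)),
            class = "hopfield_store")
}

#' @export
print.hopfield_store <- function(x, ...) {
  cat(sprintf("modern Hopfield network: %d patterns of dimension %d, beta = %g\n",
              nrow(x$patterns), ncol(x$patterns), x$beta))
  invisible(x)
}

# One batched update step for queries Q (n x D); returns n x M weights.
hopfield_weights <- function(store, Q) {
  S <- tcrossprod(Q, store$patterns)                # n x M
  S <- store$beta * (S - matrix(store$norms2 / 2, nrow(S), ncol(S),
                                byrow = TRUE))
  softmax_rows(S)
}

# Iterate a batch of queries to convergence. Returns list(patterns, weights,
# steps, converged) with one row per query.
hopfield_iterate <- function(store, Q, max_steps = 10L, tol = 1e-4) {
  n <- nrow(Q)
  steps <- integer(n)
  converged <- logical(n)
  W <- NULL
  active <- rep(TRUE, n)
  for (s in seq_len(max_steps)) {
    Wa <- hopfield_weights(store, Q[active, , drop = FALSE])
    Qnew <- Wa %*% store$patterns
    delta <- rowMeans(abs(Qnew - Q[active, , drop = FALSE]))
    Q[active, ] <- Qnew
    if (is.null(W)) W <- matrix(0, n, nrow(store$patterns))
    W[active, ] <- Wa
    steps[active] <- s
    done <- delta < tol
    converged[active][done] <- TRUE
    active[active] <- !done
    if (!any(active)) break
  }
  list(patterns = Q, weights = W, steps = steps, converged = converged)
}

#' Retrieve a memory from a query
#'
#' Iterates the MHN update until the mean absolute change falls below `tol`
#' or `max_steps` is reached.
#'
#' @param store A [hopfield_store()].
#' @param query Numeric vector of length D.
#' @param max_steps Maximum update iterations.
#' @param tol Convergence tolerance on the mean absolute change per element.
#' @return A list of class `retrieval_result`: `pattern` (length-D vector,
#'   always a convex combination of stored rows), `weights` (simplex vector
#'   over stored memories from the final step), `steps`, `converged`.
#' @export
hopfield_retrieve <- function(store, query, max_steps = 10L, tol = 1e-4) {
  stopifnot(inherits(store, "hopfield_store"))
  if (!all(is.finite(query))) stop("query must be finite")
  if (length(query) != ncol(store$patterns)) {
    stop("query length does not match stored pattern dimension")
  }
  stopifnot(max_steps >= 1L)
  r <- hopfield_iterate(store, matrix(query, nrow = 1L), max_steps, tol)
  structure(list(pattern = drop(r$patterns), weights = drop(r$weights),
                 steps = r$steps[1L], converged = r$converged[1L]),
            class = "retrieval_result")
}

#' Replay memories from random-noise queries
#'
#' Each replay sample is the result of [hopfield_retrieve()] applied to an
#' independent uniform-noise query over the store's `value_range`; a single
#' fixed set of samples is drawn per consolidation run.
#'
#' @param store A [hopfield_store()].
#' @param n Number of replay samples.
#' @param seed Optional integer seed.
#' @param max_steps,tol Retrieval controls, as in [hopfield_retrieve()].
#' @return A list: `samples` (n x D matrix of retrieved patterns), `steps`,
#'   `converged` (per-sample flags).
#' @export
hopfield_replay <- function(store, n, seed = NULL, max_steps = 10L,
                            tol = 1e-4) {
  stopifnot(inherits(store, "hopfield_store"), n >= 1L)
  use_seed(seed)
  D <- ncol(store$patterns)
  Q <- matrix(stats::runif(n * D, store$value_range[1], store$value_range[2]),
              nrow = n)
  r <- hopfield_iterate(store, Q, max_steps, tol)
  list(samples = r$patterns, steps = r$steps, converged = r$converged)
}
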