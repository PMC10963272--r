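#' @keywords internal
"_PACKAGE"

# Internal numeric helpers shared across modules.

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Flatten an image array to a vector
#'
#' Images are H x W x C arrays of floats in `[0, 1]`. Flattening order is
#' row-major with channels last (channel index varies fastest, then column,
#' then row), so that flat vectors written to CSV are portable across
#' languages that use C-order arrays.
#'
#' @param img An H x W x C numeric array (a plain H x W matrix is treated as
#'   a single-channel image).
#' @return A numeric vector of length `H * W * C`.
#' @seealso [unflatten_image()]
#' @export
flatten_image <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  stopifnot(length(dim(img)) == 3L)
  as.vector(aperm(img, c(3L, 2L, 1L)))
}

#' Restore an image array from its flat vector
#'
#' @param v Numeric vector produced by [flatten_image()].
#' @param dim Integer vector `c(height, width, channels)`.
#' @return An H x W x C numeric array.
#' @export
unflatten_image <- function(v, dim) {
  stopifnot(length(dim) == 3L, length(v) == prod(dim))
  aperm(array(v, dim = rev(dim)), c(3L, 2L, 1L))
}

# Numerically stable softmax of a vector (max subtraction).
softmax_stable <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-wise stable softmax of a matrix.
softmax_rows <- function(X) {
  m <- apply(X, 1L, max)
  E <- exp(X - m)
  E / rowSums(E)
}

# Seed the global RNG when a seed is supplied; a NULL seed leaves the
# caller's RNG stream untouched (the base-R convention for simulators).
use_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

stop_if_not_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
}
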